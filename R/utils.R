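# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# coerce labels to logical (TRUE = positive); accepts logical, 0/1 numeric,
# or the strings "positive"/"negative"
as_binary_labels <- function(labels) {
  if (is.logical(labels)) {
    lab <- labels
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    lab <- labels == 1
  } else {
    v <- tolower(as.character(labels))
    if (!all(v %in% c("positive", "negative", "pos", "neg")))
      stop("labels must be logical, 0/1, or 'positive'/'negative'")
    lab <- v %in% c("positive", "pos")
  }
  if (anyNA(lab)) stop("labels contain missing values")
  lab
}

# encode a residue string as 1-based indices into AA20; errors on other letters
encode_residues <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("seq must be a single character string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  idx <- match(chars, AA20)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("alphabet error: residue(s) %s not among the 20 standard amino acids",
                 paste(sQuote(bad), collapse = ", ")))
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
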