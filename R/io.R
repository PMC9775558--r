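# FASTA IO and the PScore-compatibility filter

#' Read protein sequences from a FASTA file
#'
#' Standard FASTA parsing (multi-line sequences joined, residues upper-cased).
#' The record id is the first whitespace-delimited token of the header; the
#' rest is kept as the description. Ids must be unique within a file.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("parse error reading ", path, ": ",
                                           conditionMessage(e)))
  if (!length(set)) stop("parse error: no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("parse error: record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id(s): ", paste(unique(dup), collapse = ", "))
  res <- toupper(as.character(set))
  empty <- !nzchar(res)
  if (any(empty)) stop("parse error: record with no residues: ", ids[empty][1L])
  data.frame(id = ids, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path output file path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Compatibility filter for externally scored sequences
#'
#' The published PScore script returns no score for sequences shorter than
#' 140 residues or containing letters outside the 20 standard amino-acid
#' codes; such sequences must be removed before composite scoring. This
#' filter never errors: it partitions the input into kept and dropped records
#' and records a reason per dropped id (`too_short`, `nonstandard_letter`, or
#' both joined by `;`).
#'
#' @param records data frame with columns `id` and `residues`.
#' @param min_len minimum accepted length (residues); default 140.
#' @return A list with `kept` (data frame, same columns as the input) and
#'   `dropped` (data frame: `id`, `reason`).
#' @export
filter_sequences <- function(records, min_len = 140L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  if (!nrow(records))
    return(list(kept = records,
                dropped = data.frame(id = character(0), reason = character(0),
                                     stringsAsFactors = FALSE)))
  too_short <- nchar(records$residues) < min_len
  bad_alpha <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")),
                     toupper(records$residues))
  drop <- too_short | bad_alpha
  reason <- mapply(function(ts, ba) {
    paste(c(if (ts) "too_short", if (ba) "nonstandard_letter"), collapse = ";")
  }, too_short[drop], bad_alpha[drop])
  list(kept = records[!drop, , drop = FALSE],
       dropped = data.frame(id = records$id[drop],
                            reason = as.character(reason),
                            stringsAsFactors = FALSE))
}
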