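>pos_001 synthetic
TTDGDQAPRYKDNEKSPFEPYNSGGPKGEEQYENSYKKRGGTSYRSSKPRKRPQPDNNDW
NPSTALTLQNNTSEPFPRRISLGKESPYPETNGTSIFFFARGSSRCESQAAIAQGDGESQ
TNQKPSPGTTQKKLKPLTLTAEKPSKEK
>pos_002 synthetic
VPAQTCTHSDPIQRHMRNLPHRKTGSTSDEESGTYKPHEKDQTTISATRKGNQKSDGQFS
TKKKKELERNETTQEPTGNKTAEESKTEPTEKENGDLRSTEPDTKHSPNRSDFGVKYDGS
ESGSSTDPRTGMPAGKGYGSILVFIFRDGESNPEIRGSDPQ
>pos_003 synthetic
RREESEQRSSPLGSRYNEPPAFVVLLVVESNEESQQPDPNEPKQKCKRFEDGPEYPDSEY
QTTAIPTEKSKNSAPFENATNDKSDWDGKELVSGRKQNHRRNDKKRPGHKHVDQKVRSTT
GTAQQGRPTGRKRGTQADREGGPDTQAQKERSTSSPDSKPTSSPQHPTEKGDGTNPGQS
>pos_004 synthetic
TKMDRRDKKSDKEILFLVEAPASTDHDSEPKDSHSNSCDTNTADSPGNNQSGGGGKYSGV
PQPNRKGKREGAGESQGKAEDGKEEKPSSTAQGPDGTRSNPQLDSTKEITGSNTPRTCES
QSERTRQTQESEPAKRGAHKGCSPLQPRNT
>pos_005 synthetic
ELPHNGGNNKTITSVSGGDSSGARDVSVALAERSSGGSGEHAEGGGRDIPFHSQSQEEQP
KNDTADRRPTSRTEPEDETPKSPNCAPQASTTRLTVDSHGGKDKASESTSSKTKGFVVFS
SGPNQSEISKQRLSEDTGGETSAKFDKHRNESS
>neg_001 synthetic
NPYLSTKKKKTHETSSEEERSDRDNRDEYYYTGQPDEPAGQGPQGKANDLNGKSDDTESG
VSPDRSDKGDPSDGDQFSEGKQGRSSESTGSSTSSPPRNSKADIDKQGNRNGKEGGTNSN
AFQALGAPSEEKWEDHQKTECEKEKELSNKSELDPSESDTQGWTAKKDEPTTDDQGDAH
>neg_002 synthetic
DQLQKQNRDEETSTPKTTNDDKRADLCGWNSRQMGSEAKTDYGEEKQEFDQAREEPRRES
TDDSNYSFTDDEEREEMEEQPREKLQNGGFRSSDVTESSPRFKQSNAKGKGETHNAWTRF
SDPKSPITTDDDEETPSTTSPK
>neg_003 synthetic
PQLTNGQNRRPESKTRRSGQGEKQEERQNFQARGAENGTENTQSSQSAEDRLLQDDKQST
ESQASEGEGYQEYDLDGLLEPQFTDSQEPEEEPKPKEKDTGPDAASNQIKGQDKSAKSKG
KRGGPGTESTIQNTQEASAPRDESEKSSAQEPNESNGQPDG
>neg_004 synthetic
RGRGRRDNHDRQRKSLSYAEQQGQYKNGRPRPYEHRLDSDRGRQDSSPDNTKEQFPPTME
TSPTRQNQTRRQTQGGETDDGPSLPYTTQDPEQAGRTRKEPDGKPNDGIDQGKSNGNTGN
GTSGGSSSDGVLSKPSKPEILSVVPSSKS
>neg_005 synthetic
YNNTKQGDRQTDSTETQEGSRGCQGLGKQGPSKAAGITASSSGYSTKNSRLPEKKNQSMS
EPLPGGPSDEGTIAKALEQKSRESDSPSFVPSTPSQDGQSNTRGDKRKEKNGNGNSGPRP
WSNDKDEDPGTNPRFKHIHNE
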