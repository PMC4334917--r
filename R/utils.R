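# internal helpers shared across modules

# deterministic metabolite ids for a pathway layout: M0001.. in pathway order
.metaboliteIds <- function(sizes) sprintf("M%04d", seq_len(sum(sizes)))

# named assignment vector metabolite -> pathway for a pathway-size layout
.assignmentFromSizes <- function(sizes) {
  stats::setNames(rep(names(sizes), times = sizes), .metaboliteIds(sizes))
}

# Mann-Whitney identity: P(score[planted] > score[null]) with tie correction
.rankAuroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both planted and null metabolites")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# read a delimited text file, TSV default with comma fallback
.readDelim <- function(path, header = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = header, sep = sep, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "", comment.char = "")
}
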