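#' @useDynLib splicewalk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits runValue runLength
#' @importFrom stats rgamma runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N, either case).
#' @return character vector of reverse complements (uppercase preserved).
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

## Run code with a deterministic, locally-scoped RNG state. The caller's
## .Random.seed is saved and restored so library functions never perturb the
## session RNG.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

## CIGAR helpers ------------------------------------------------------------

#' Parse a CIGAR string into operation lengths and codes
#'
#' @param cigar a CIGAR string, e.g. "50M150N60M".
#' @return data.frame with columns `len` (integer) and `op` (character).
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    return(data.frame(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

## Collapse adjacent same-op runs and drop zero-length ops.
cigar_string <- function(len, op) {
  keep <- len > 0
  len <- len[keep]; op <- op[keep]
  if (length(op) == 0) return("")
  grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
  len <- vapply(split(len, grp), sum, numeric(1))
  op <- vapply(split(op, grp), `[`, character(1), 1)
  paste0(as.integer(len), op, collapse = "")
}

## Total query-consuming length of a CIGAR (M/I/S/=/X).
cigar_qlen <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "I", "S", "=", "X")])
}

## Per-base mapping of query positions to 0-based genome positions.
## Returns an integer vector of length qlen; NA for bases not on the
## reference (insertions, soft clips).
cigar_base_positions <- function(pos, cigar) {
  co <- cigar_ops(cigar)
  out <- rep(NA_integer_, sum(co$len[co$op %in% c("M", "I", "S", "=", "X")]))
  qi <- 0L; gi <- pos
  for (i in seq_len(nrow(co))) {
    len <- co$len[i]; op <- co$op[i]
    if (op %in% c("M", "=", "X")) {
      out[(qi + 1):(qi + len)] <- gi + 0:(len - 1)
      qi <- qi + len; gi <- gi + len
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    } else if (op %in% c("D", "N")) {
      gi <- gi + len
    }
  }
  out
}

## Merge sorted intervals (matrix with cols start, end; 0-based half-open)
## that overlap or abut within `gap`.
merge_intervals <- function(start, end, gap = 0L) {
  if (length(start) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  os <- start[1]; oe <- end[1]
  rs <- integer(0); re <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= oe + gap) oe <- max(oe, end[i])
    else { rs <- c(rs, os); re <- c(re, oe); os <- start[i]; oe <- end[i] }
  }
  data.frame(start = c(rs, os), end = c(re, oe))
}
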