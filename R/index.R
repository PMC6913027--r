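## Reference de Bruijn graph (RdBG) index: unitigs of the graph over all
## N-free genomic k-mers, their genomic occurrence runs, and an l-mer seed
## table over the unitig sequences. The index is built on the forward genome
## only; reverse-strand reads are handled by seeding the read's reverse
## complement (see the skeleton module).

#' Build the reference de Bruijn graph index
#'
#' Unitigs are the maximal non-branching paths of the de Bruijn graph over
#' all N-free k-mers of the reference. Each unitig carries a list of genomic
#' occurrence runs: a run records a maximal stretch of consecutive genome
#' positions whose k-mers map to consecutive offsets of that unitig, so the
#' union of all run footprints covers every N-free genomic k-mer position
#' exactly. An l-mer seed table over the unitig sequences supports first-pass
#' seeding with seeds shorter than k.
#'
#' Unitigs whose occurrence list exceeds `repeat_cap` are marked highly
#' repetitive and their seeds are ignored during skeleton generation.
#'
#' @param reference named character vector of chromosome sequences.
#' @param k k-mer size of the graph (2 < k <= 31), default 22.
#' @param l seed length used in the first alignment pass (2 <= l < k),
#'   default 15.
#' @param repeat_cap occurrence-count threshold above which a unitig is
#'   treated as repetitive (default 300).
#' @return object of class `rdbg_index`.
#' @export
build_index <- function(reference, k = 22L, l = 15L, repeat_cap = 300L) {
  if (length(reference) == 0 || sum(nchar(reference)) == 0)
    stop("empty reference")
  if (!(k >= 3 && k <= 31)) stop("k must be in [3, 31]")
  if (!(l >= 2 && l < k)) stop("l must satisfy 2 <= l < k")
  if (any(nchar(reference) < k)) stop("all chromosomes must be >= k bases")
  raw <- cpp_build_index(unname(reference), as.integer(k))
  occ <- data.frame(uid = raw$uid + 1L,
                    chrom = names(reference)[raw$chrom + 1L],
                    gstart = raw$gstart, uoff = raw$uoff, nk = raw$nk,
                    stringsAsFactors = FALSE)
  idx <- structure(list(
    k = as.integer(k), l = as.integer(l),
    repeat_cap = as.integer(repeat_cap),
    unitigs = raw$unitigs,
    occ = occ,
    chroms = setNames(nchar(reference), names(reference)),
    checksum = ref_checksum(reference),
    ptr_env = new.env(parent = emptyenv())),
    class = "rdbg_index")
  idx
}

ref_checksum <- function(reference) {
  ## cheap order-sensitive rolling checksum; enough to catch index/reference
  ## mismatches at load time
  s <- paste(names(reference), nchar(reference),
             substr(reference, 1, 50), collapse = "|")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 2147483647
}

## Lazily (re)build the C++ seed table behind the serializable R object.
index_ptr <- function(index) {
  p <- index$ptr_env$ptr
  if (is.null(p) || !cpp_ptr_valid(p)) {
    p <- cpp_make_seed_index(index$unitigs, index$occ$uid - 1L,
                             index$k, index$l, index$repeat_cap)
    index$ptr_env$ptr <- p
  }
  p
}

#' @export
print.rdbg_index <- function(x, ...) {
  cat(sprintf(paste0("RdBG index: k=%d l=%d | %d unitigs, %d occurrence ",
                     "runs | %d chromosome(s), %d bp\n"),
              x$k, x$l, length(x$unitigs), nrow(x$occ),
              length(x$chroms), sum(x$chroms)))
  invisible(x)
}

#' Look up an l-mer seed in the index
#'
#' @param index an `rdbg_index`.
#' @param seed an l-mer (N-free), `nchar(seed) == index$l`.
#' @return data.frame with columns `uid` and `uoff`: every unitig position
#'   whose l-mer equals the seed (empty when absent).
#' @export
lookup_seed <- function(index, seed) {
  if (nchar(seed) != index$l)
    stop("seed length ", nchar(seed), " != l = ", index$l)
  m <- cpp_lookup_seed(index_ptr(index), toupper(seed))
  data.frame(uid = m[, 1] + 1L, uoff = m[, 2])
}

#' Project a unitig interval onto the genome
#'
#' Maps a half-open interval on a unitig to all genomic intervals where
#' that part of the unitig occurs, via the occurrence runs. Intervals not
#' fully contained in a run are not reported for that run.
#'
#' @param index an `rdbg_index`.
#' @param uid unitig id (1-based).
#' @param start,end 0-based half-open interval within the unitig.
#' @return data.frame with columns chrom, gstart, gend.
#' @export
unitig_to_genome <- function(index, uid, start, end) {
  ulen <- nchar(index$unitigs[uid])
  if (start < 0 || end > ulen || start >= end)
    stop("interval out of unitig bounds")
  runs <- index$occ[index$occ$uid == uid, , drop = FALSE]
  k <- index$k
  out <- lapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    span_s <- r$uoff                      # unitig bases covered by the run
    span_e <- r$uoff + r$nk + k - 1L
    if (start >= span_s && end <= span_e) {
      gs <- r$gstart + (start - r$uoff)
      data.frame(chrom = r$chrom, gstart = gs, gend = gs + (end - start),
                 stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), gstart = integer(0),
                      gend = integer(0), stringsAsFactors = FALSE)
  out
}

#' Save an index to disk
#'
#' The on-disk form embeds k, l and a reference checksum and round-trips
#' losslessly (the l-mer hash table is rebuilt on load).
#'
#' @param index an `rdbg_index`.
#' @param path file path (RDS).
#' @export
save_index <- function(index, path) {
  obj <- index[c("k", "l", "repeat_cap", "unitigs", "occ", "chroms",
                 "checksum")]
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' Load an index saved by [save_index()]
#'
#' @param path file path.
#' @param reference optional reference to validate the stored checksum
#'   against.
#' @return an `rdbg_index`.
#' @export
load_index <- function(path, reference = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) stop("unknown index version")
  if (!is.null(reference) && obj$checksum != ref_checksum(reference))
    stop("index was built from a different reference")
  idx <- structure(c(obj[c("k", "l", "repeat_cap", "unitigs", "occ",
                           "chroms", "checksum")],
                     list(ptr_env = new.env(parent = emptyenv()))),
                   class = "rdbg_index")
  idx
}
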