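#' Genetic map of biallelic markers
#'
#' A genetic map assigns every marker to one chromosome and an ordered
#' position in centimorgans. Positions must be non-decreasing within a
#' chromosome.
#'
#' @param chr integer or character vector, chromosome of each marker.
#' @param pos_cM numeric vector, genetic position of each marker (cM).
#' @param marker optional character vector of marker names.
#' @return An object of class `genetic_map`: a data frame with columns
#'   `marker`, `chr`, `pos_cM`, ordered by (chromosome, position), plus
#'   attributes `chr_first`/`chr_last` (1-based index ranges per chromosome).
#' @examples
#' gm <- genetic_map(rep(1:2, each = 3), c(0, 10, 50, 0, 25, 80))
#' total_map_length(gm)
#' @export
genetic_map <- function(chr, pos_cM, marker = NULL) {
  stopifnot(length(chr) == length(pos_cM), is.numeric(pos_cM), !anyNA(pos_cM))
  if (is.null(marker)) marker <- paste0("m", seq_along(chr))
  chr_f <- factor(chr, levels = unique(chr))
  o <- order(as.integer(chr_f), pos_cM)
  df <- data.frame(marker = as.character(marker)[o], chr = chr[o],
                   pos_cM = pos_cM[o], stringsAsFactors = FALSE)
  if (anyDuplicated(df$marker)) stop("duplicated marker names in map")
  rle_chr <- rle(as.character(df$chr))
  last <- cumsum(rle_chr$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  structure(df, class = c("genetic_map", "data.frame"),
            chr_first = first, chr_last = last, chr_names = rle_chr$values)
}

#' @rdname genetic_map
#' @param x a `genetic_map`.
#' @export
total_map_length <- function(x) {
  stopifnot(inherits(x, "genetic_map"))
  f <- attr(x, "chr_first"); l <- attr(x, "chr_last")
  sum(x$pos_cM[l] - x$pos_cM[f])
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers on %d chromosomes, %.1f cM total\n",
              nrow(x), length(attr(x, "chr_first")), total_map_length(x)))
  invisible(x)
}

n_chromosomes <- function(map) length(attr(map, "chr_first"))

# 0-based inclusive index ranges and positions in Morgans, as the meiosis
# kernel expects them.
map_for_cpp <- function(map) {
  list(first = attr(map, "chr_first") - 1L,
       last = attr(map, "chr_last") - 1L,
       pos_m = map$pos_cM / 100)
}

#' Species-like default maps
#'
#' Evenly spaced marker maps emulating the chromosome number and total map
#' length of the SNP panels used in temperate maize (10 chromosomes, 1,442 cM)
#' and spring bread wheat (21 chromosomes, 3,009 cM) hybrid breeding programs.
#'
#' @param n_markers total marker count, split evenly across chromosomes.
#' @return A [genetic_map].
#' @examples
#' maize_like_map(500)
#' @export
maize_like_map <- function(n_markers = 2000) {
  even_map(n_chr = 10, total_cM = 1442, n_markers = n_markers)
}

#' @rdname maize_like_map
#' @export
wheat_like_map <- function(n_markers = 2000) {
  even_map(n_chr = 21, total_cM = 3009, n_markers = n_markers)
}

#' @rdname maize_like_map
#' @param n_chr number of chromosomes.
#' @param total_cM total map length in centimorgans.
#' @export
even_map <- function(n_chr, total_cM, n_markers) {
  stopifnot(n_chr >= 1, total_cM > 0, n_markers >= n_chr)
  per <- diff(round(seq(0, n_markers, length.out = n_chr + 1)))
  chr_len <- total_cM / n_chr
  chr <- rep(seq_len(n_chr), per)
  pos <- unlist(lapply(per, function(k) seq(0, chr_len, length.out = k)))
  genetic_map(chr, pos)
}
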