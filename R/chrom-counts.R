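#' Canonical human chromosome names
#'
#' @return Character vector `"1".."22", "X", "Y"`.
#' @export
canonical_chromosomes <- function() c(as.character(1:22), "X", "Y")

#' hg19 chromosome lengths
#'
#' Reference lengths (bp) of the 24 canonical human chromosomes in the hg19 /
#' GRCh37 assembly, used by the synthetic count generator and available for
#' constructing count tables in tests.
#'
#' @return Named integer-valued numeric vector over [canonical_chromosomes()].
#' @export
hg19_chromosome_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

#' Per-chromosome mapped read counts for one sample
#'
#' The substrate of the Ry and Rx statistics: for each of the 24 canonical
#' chromosomes, its reference length and the number of mapped reads.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp); names must
#'   cover all of [canonical_chromosomes()].
#' @param mapped Named numeric vector of mapped read counts, same names.
#' @param sample_id Sample identifier.
#'
#' @return An object of class `chrom_counts`: a data frame with columns
#'   `chrom`, `length_bp`, `mapped`, ordered 1..22, X, Y, with attribute
#'   `sample_id`.
#' @examples
#' cc <- chrom_counts(hg19_chromosome_lengths(),
#'                    setNames(rep(1000, 24), canonical_chromosomes()), "S1")
#' total_mapped(cc)
#' @export
chrom_counts <- function(lengths, mapped, sample_id = "sample") {
  canon <- canonical_chromosomes()
  missing_len <- setdiff(canon, names(lengths))
  missing_map <- setdiff(canon, names(mapped))
  if (length(missing_len) || length(missing_map)) {
    stop("missing canonical chromosome(s): ",
         paste(union(missing_len, missing_map), collapse = ", "), call. = FALSE)
  }
  lengths <- as.numeric(lengths[canon])
  mapped <- as.numeric(mapped[canon])
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (any(!is.finite(mapped)) || any(mapped < 0)) {
    stop("mapped read counts must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(chrom = canon, length_bp = lengths, mapped = mapped,
               stringsAsFactors = FALSE),
    sample_id = as.character(sample_id),
    class = c("chrom_counts", "data.frame")
  )
}

#' Total mapped reads across the 24 canonical chromosomes
#'
#' @param counts A [chrom_counts()] object.
#' @return Numeric scalar.
#' @export
total_mapped <- function(counts) {
  stopifnot(inherits(counts, "chrom_counts"))
  sum(counts$mapped)
}

#' Read a samtools-idxstats table into canonical chromosome counts
#'
#' Parses the four-column, headerless per-chromosome summary (name, length,
#' mapped, unmapped) produced by standard alignment toolchains. Chromosome
#' names are normalized to the un-prefixed canonical dialect ("chrX" -> "X",
#' "23"/"24" -> "X"/"Y"); unplaced scaffolds, the mitochondrion and the
#' unmapped-only "*" row are dropped and tallied in a discard report. The
#' unmapped column is parsed but ignored: the ratio statistics use mapped
#' reads only.
#'
#' @param path Path to the TSV.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#'
#' @return A [chrom_counts()] object with attribute `discards` (character
#'   vector of dropped row names).
#' @export
read_idxstats <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           comment.char = "", quote = "")
  if (ncol(raw) < 3) stop("idxstats file needs >= 3 columns: ", path, call. = FALSE)
  name <- normalize_chrom_names(raw[[1]])
  keep <- !is.na(name)
  discards <- raw[[1]][!keep]
  lens <- suppressWarnings(as.numeric(raw[[2]][keep]))
  maps <- suppressWarnings(as.numeric(raw[[3]][keep]))
  if (any(is.na(lens)) || any(is.na(maps))) {
    stop("non-numeric length/mapped field in ", path, call. = FALSE)
  }
  if (any(maps < 0)) stop("negative mapped count in ", path, call. = FALSE)
  nm <- name[keep]
  if (any(duplicated(nm))) {
    stop("duplicated chromosome rows in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(canonical_chromosomes(), nm)
  if (length(missing)) {
    stop("idxstats file ", path, " lacks canonical chromosome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cc <- chrom_counts(stats::setNames(lens, nm), stats::setNames(maps, nm),
                     sample_id = sample_id)
  attr(cc, "discards") <- discards
  cc
}

# "chr1"/"1" -> "1"; "chrX"/"X"/"23" -> "X"; "chrY"/"Y"/"24" -> "Y";
# anything else (scaffolds, chrM/MT, "*") -> NA.
normalize_chrom_names <- function(x) {
  bare <- sub("^chr", "", x)
  bare[bare == "23"] <- "X"
  bare[bare == "24"] <- "Y"
  bare[!bare %in% canonical_chromosomes()] <- NA_character_
  bare
}

#' @export
print.chrom_counts <- function(x, ...) {
  cat(sprintf("chrom_counts for %s: %s mapped reads (%s on X, %s on Y)\n",
              attr(x, "sample_id"),
              format(sum(x$mapped), big.mark = ","),
              format(x$mapped[x$chrom == "X"], big.mark = ","),
              format(x$mapped[x$chrom == "Y"], big.mark = ",")))
  invisible(x)
}
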