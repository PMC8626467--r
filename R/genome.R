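# Genome coordinate model. All coordinates in the package are 1-based, fully
# closed intervals (VCF / Battenberg convention); converters live only at
# format boundaries.

# GRCh37 autosome lengths (bp). Sex chromosomes are excluded by default: the
# copy-number landscape analysed here is autosome-dominated and allele-specific
# states on X/Y need sex-aware baselines.
GRCH37_AUTOSOMES <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566
)

# Classical MHC / HLA locus on 6p21 (GRCh37), used by region filtering.
HLA_REGION_GRCH37 <- tibble::tibble(
  chrom = "6", start = 28477797, end = 33448354, label = "HLA"
)

#' Construct a genome model
#'
#' A genome model holds the ordered chromosome set, chromosome lengths and any
#' excluded regions (for example the HLA locus on 6p21, which recurrent
#' copy-number calls are filtered against). Two presets are bundled: the
#' GRCh37 autosomes and a three-chromosome 10-Mb "toy" genome used throughout
#' the test-suite and the simulator defaults.
#'
#' @param name `"toy"` or `"grch37"`, or `NULL` when supplying
#'   `chrom_lengths` directly.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp
#'   (names are chromosome identifiers; a `"chr"` prefix is stripped).
#' @param excluded_regions Tibble with columns `chrom`, `start`, `end`,
#'   `label`, or `NULL` for none. The GRCh37 preset bundles the HLA region.
#' @return An object of class `genome_model`: a list with `chrom_names`,
#'   `chrom_lengths` (named, bp) and `excluded_regions` (tibble).
#' @examples
#' g <- genome_model("toy")
#' g$chrom_lengths
#' @export
genome_model <- function(name = c("toy", "grch37"), chrom_lengths = NULL,
                         excluded_regions = NULL) {
  if (is.null(chrom_lengths)) {
    name <- match.arg(name)
    if (name == "toy") {
      chrom_lengths <- c(`1` = 1e7, `2` = 1e7, `3` = 1e7)
      if (is.null(excluded_regions)) {
        excluded_regions <- tibble::tibble(
          chrom = character(), start = numeric(), end = numeric(),
          label = character()
        )
      }
    } else {
      chrom_lengths <- GRCH37_AUTOSOMES
      if (is.null(excluded_regions)) excluded_regions <- HLA_REGION_GRCH37
    }
  } else {
    if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths))) {
      stop("chrom_lengths must be a named vector", call. = FALSE)
    }
    names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
    if (is.null(excluded_regions)) {
      excluded_regions <- tibble::tibble(
        chrom = character(), start = numeric(), end = numeric(),
        label = character()
      )
    }
  }
  if (any(chrom_lengths <= 0)) {
    stop("all chromosome lengths must be > 0", call. = FALSE)
  }
  excluded_regions$chrom <- normalize_chrom(excluded_regions$chrom)
  bad <- !excluded_regions$chrom %in% names(chrom_lengths) |
    excluded_regions$start < 1 |
    excluded_regions$end > chrom_lengths[excluded_regions$chrom] |
    excluded_regions$start > excluded_regions$end
  if (any(bad)) {
    stop("excluded regions must lie within their chromosome", call. = FALSE)
  }
  structure(
    list(
      chrom_names = names(chrom_lengths),
      chrom_lengths = chrom_lengths,
      excluded_regions = excluded_regions
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chrom_names), " chromosomes, ",
    format(sum(x$chrom_lengths), big.mark = ","), " bp, ",
    nrow(x$excluded_regions), " excluded region(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chr1"` and `"1"` compare equal;
#' all internal tables use the unprefixed form.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector without `"chr"` prefixes.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Tile a genome into fixed-width bins
#'
#' Partitions every chromosome into consecutive non-overlapping bins starting
#' at position 1. The final partial bin of each chromosome is retained, so the
#' tiling covers the genome exactly.
#'
#' @param genome A [genome_model()].
#' @param width Bin width in bp (default 100 kb, the hotspot-scan resolution).
#' @return Tibble with columns `chrom`, `start`, `end` (1-based, closed).
#' @examples
#' nrow(bin_genome(genome_model("toy"), width = 1e5)) # 300 bins
#' @export
bin_genome <- function(genome, width = 100000) {
  stopifnot(inherits(genome, "genome_model"))
  if (length(width) != 1 || !is.finite(width) || width <= 0) {
    stop("width must be a single positive number", call. = FALSE)
  }
  purrr::map_dfr(genome$chrom_names, function(ch) {
    len <- unname(genome$chrom_lengths[[ch]])
    start <- seq(1, len, by = width)
    tibble::tibble(chrom = ch, start = start, end = pmin(start + width - 1, len))
  })
}
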