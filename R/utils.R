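#' @keywords internal
"_PACKAGE"

# The nine agronomic traits scored in the trial, with units and typical
# high-latitude japonica magnitudes used as simulation defaults.
TRAIT_INFO <- data.frame(
  trait = c("DW", "PH", "TN", "GN", "TGW", "SR", "PL", "PW", "DH"),
  unit  = c("g", "cm", "count", "count", "g", "proportion", "cm", "g", "days"),
  mean  = c(25, 95, 15, 1500, 25, 0.85, 18, 3, 100),
  stringsAsFactors = FALSE
)

#' Trait names used throughout the pipeline
#' @return Character vector of the nine trait codes.
#' @export
trait_names <- function() TRAIT_INFO$trait

# Derive independent sub-stream seeds from one master seed so that, e.g.,
# phenotype noise can be re-drawn without perturbing the genotypes.
derive_seeds <- function(seed, n = 8L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Long phenotype records -> accession x trait matrix for one (year, treatment)
pheno_wide <- function(table, year, treatment) {
  sub <- table[table$year == year & table$treatment == treatment, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for year ", year, " treatment ", treatment)
  traits <- unique(sub$trait)
  acc <- unique(sub$accession)
  m <- matrix(NA_real_, length(acc), length(traits),
              dimnames = list(acc, traits))
  m[cbind(match(sub$accession, acc), match(sub$trait, traits))] <- sub$value
  m
}

# dense descending ranks, ties share a rank, stable by name order
dense_rank_desc <- function(x) {
  ux <- sort(unique(x), decreasing = TRUE)
  match(x, ux)
}
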