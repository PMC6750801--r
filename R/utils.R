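#' @keywords internal
"_PACKAGE"

## round half up (base round() is round-half-even, which does not match the
## convention used for reported cohort percentages)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  ## epsilon guards against binary representation of decimals (6.65 * 10
  ## is 66.4999...), appropriate for display rounding
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

## run `expr` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Controlled vocabulary of taxon abbreviations
#'
#' Maps the short taxon labels used in figures and score formulas of vaginal
#' microbiome studies to the canonical labels used throughout this package.
#'
#' @return Named character vector: names are abbreviations, values canonical
#'   taxon labels.
#' @examples
#' taxon_vocab()[["Samn"]]
#' @export
taxon_vocab <- function() {
  c(Samn   = "Sneathia_amnii",
    BVAB1  = "Lachnospiraceae_BVAB1",
    TM7    = "TM7_H1",
    Pcl2   = "Prevotella_cluster2",
    Lcricl = "Lactobacillus_crispatus_cluster",
    Liners = "Lactobacillus_iners",
    Gvag   = "Gardnerella_vaginalis",
    Avag   = "Atopobium_vaginae",
    Mega1  = "Megasphaera_OTU70_type1",
    Dcl51  = "Dialister_cluster51",
    Dmic   = "Dialister_micraerophilus",
    Pamn   = "Prevotella_amnii",
    BVAB2  = "Clostridiales_BVAB2",
    CO27   = "Coriobacteriaceae_OTU27",
    P142   = "Parvimonas_OTU142",
    Ssan   = "Sneathia_sanguinegens")
}

## canonicalize a taxon name: accept either canonical label or abbreviation
canonical_taxon <- function(x) {
  v <- taxon_vocab()
  ifelse(x %in% v, x, ifelse(x %in% names(v), unname(v[x]), x))
}
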