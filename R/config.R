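#' Run configuration for the ERV pipeline
#'
#' Bundles every tunable parameter of the pipeline with its default value.
#' Defaults mirror the study conditions the pipeline is built around: a
#' canonical LTR of 457 bp, 5-bp target site duplications, a neutral host
#' substitution rate of 1.33e-9 changes per site per year, at least two
#' supporting read pairs per insertion call, a +/- 500 bp exclusion zone
#' around annotated ERVs, a 200 bp assembly window, at least 30 bp of
#' LTR-derived and genomic sequence per junction, insert-size outliers at
#' median + 7 * MAD with mapping quality >= 20, solo-LTR/provirus deletion
#' size classes of 400-500 bp and 7-9 kb, and 1000 permutations over gene
#' windows of 0, 5, 10, 25, 50, and 100 kb.
#'
#' @param ... Named overrides for any default listed below.
#'
#' @return An object of class `erv_config`: a named list with elements
#'   `rate_per_site_year`, `ltr_length`, `tsd_length`, `flank_bp`,
#'   `min_support_pairs`, `known_erv_exclusion_bp`, `assembly_window_bp`,
#'   `min_junction_bp`, `deletion_mad_cutoff`, `deletion_min_mapq`,
#'   `solo_size_range`, `provirus_size_range`, `permutations`, `windows_kb`,
#'   `seed`, plus mapper/assembler knobs (`map_k`, `map_min_identity`,
#'   `min_identity`, `min_anchor_bp`, `assembly_min_overlap`,
#'   `assembly_min_identity`) and `rate_presets` (alternative published
#'   substitution rates, per site per year).
#'
#' @examples
#' cfg <- erv_config()
#' cfg$rate_per_site_year
#' erv_config(permutations = 100)$permutations
#' @export
erv_config <- function(...) {
  cfg <- list(
    rate_per_site_year   = 1.33e-9,
    ltr_length           = 457L,
    tsd_length           = 5L,
    flank_bp             = 600L,
    min_support_pairs    = 2L,
    known_erv_exclusion_bp = 500L,
    assembly_window_bp   = 200L,
    min_junction_bp      = 30L,
    deletion_mad_cutoff  = 7,
    deletion_min_mapq    = 20L,
    solo_size_range      = c(400, 500),
    provirus_size_range  = c(7000, 9000),
    permutations         = 1000L,
    windows_kb           = c(0, 5, 10, 25, 50, 100),
    seed                 = NULL,
    # mapper / anchor / assembler knobs (not stated by the study; see vignette)
    map_k                = 20L,
    map_min_identity     = 0.9,
    min_identity         = 0.9,
    min_anchor_bp        = 30L,
    assembly_min_overlap = 25L,
    assembly_min_identity = 0.95,
    rate_presets = c(dog = 1.33e-9, dog_low = 1.3e-9,
                     mammalian = 2.2e-9, mouse = 4.5e-9)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "erv_config")
}

#' @export
print.erv_config <- function(x, ...) {
  cat("ERV pipeline configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                paste(format(v, digits = 6), collapse = ", ")))
  }
  invisible(x)
}

# evaluate expr under a temporary RNG seed (no-op when seed is NULL)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}
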