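#' Registry of the relationship-matrix constructions
#'
#' Enumerates the 15 supported (source, ploidy, parametrization, method)
#' combinations: four pedigree-based constructions, nine marker-based ones
#' and two single-step blends, together with the function call that builds
#' each.
#'
#' @return data.frame with one row per construction.
#' @export
method_grid <- function() {
  g <- function(source, ploidy, parametrization, method, fun, arguments)
    data.frame(source = source, ploidy = ploidy, parametrization = parametrization,
               method = method, fun = fun, arguments = arguments,
               stringsAsFactors = FALSE)
  rbind(
    g("Pedigree (A)", "diploid",   "additive",    "tabular",        "Amatrix",  "default"),
    g("Pedigree (A)", "diploid",   "nonadditive", "dominance",      "Amatrix",  "dominance = TRUE"),
    g("Pedigree (A)", "polyploid", "additive",    "kerr",           "Amatrix",  "ploidy = m, w = w"),
    g("Pedigree (A)", "polyploid", "additive",    "slater",         "Amatrix",  "ploidy = m, slater = TRUE"),
    g("Genomic (G)",  "diploid",   "additive",    "yang",           "Gmatrix",  "method = 'Yang'"),
    g("Genomic (G)",  "diploid",   "additive",    "vanraden",       "Gmatrix",  "method = 'VanRaden'"),
    g("Genomic (G)",  "diploid",   "additive",    "liu_weighted",   "Gmatrix",  "method = 'Liu', weights"),
    g("Genomic (G)",  "diploid",   "nonadditive", "su",             "Gmatrix",  "method = 'Su'"),
    g("Genomic (G)",  "diploid",   "nonadditive", "vitezica",       "Gmatrix",  "method = 'Vitezica'"),
    g("Genomic (G)",  "polyploid", "additive",    "slater_full",    "Gmatrix",  "ploidy = m, method = 'Slater'"),
    g("Genomic (G)",  "polyploid", "additive",    "vanraden",       "Gmatrix",  "ploidy = m, method = 'VanRaden'"),
    g("Genomic (G)",  "polyploid", "nonadditive", "endelman",       "Gmatrix",  "ploidy = m, method = 'Endelman'"),
    g("Genomic (G)",  "polyploid", "ratio",       "vanraden_ratio", "Gmatrix",  "ploidy = m, method = 'VanRaden', ratio = TRUE"),
    g("Hybrid (H)",   "any",       "additive",    "martini",        "Hmatrix",  "method = 'Martini', tau, omega"),
    g("Hybrid (H)",   "any",       "additive",    "munoz",          "Hmatrix",  "method = 'Munoz'")
  )
}
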