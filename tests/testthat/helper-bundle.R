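# shared fixture objects; built once per test run
.bundle <- load_fixtures()
.drugs <- bundle_drugs(.bundle)
.thermo <- thermo_config()

wt_params_for <- function(drug_name) {
  build_parameter_set(bundle_variant(.bundle, "Wild-type"),
                      .drugs[[drug_name]], .thermo)
}

params_for <- function(variant_name, drug_name) {
  wt <- wt_params_for(drug_name)
  if (variant_name == "Wild-type") return(wt)
  build_parameter_set(bundle_variant(.bundle, variant_name),
                      .drugs[[drug_name]], .thermo, wt)
}

# tolerance of one unit in the last printed digit of a formatted value
# ("203.6" -> 0.1, "1338" -> 1, "6.01e-3" -> 1e-5)
printed_tol <- function(printed) {
  vapply(as.character(printed), function(s) {
    expo <- 0
    if (grepl("[eE]", s)) {
      expo <- as.numeric(sub("^.*[eE]", "", s))
      s <- sub("[eE].*$", "", s)
    }
    dec <- if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0L
    10^(expo - dec)
  }, numeric(1), USE.NAMES = FALSE)
}
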