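# Shared constants and small helpers.

# 1 elementary charge per picosecond expressed in nanoamperes,
# carried to 7 significant figures.
E_PER_PS_TO_NA <- 160.2177

# SI conversions used by the kinetics module.
ELEMENTARY_CHARGE_C <- 1.602177e-19  # C per e
KDA_TO_KG <- 1.66053907e-24          # kg per kDa
ANGSTROM_TO_M <- 1e-10

`%||%` <- rlang::`%||%`

stop_porepass <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "porepass_error"), ...)
}

# Validate a single finite numeric scalar.
check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_porepass(sprintf("`%s` must be a single finite number.", name),
                  "porepass_input_error")
  }
  if (positive && x <= 0) {
    stop_porepass(sprintf("`%s` must be > 0.", name), "porepass_input_error")
  }
  invisible(x)
}

porepass_extdata <- function(file) {
  path <- system.file("extdata", file, package = "porepass")
  if (!nzchar(path)) {
    stop_porepass(sprintf("packaged data file '%s' not found", file),
                  "porepass_data_error")
  }
  path
}
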