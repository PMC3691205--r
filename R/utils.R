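# Shared internal helpers.

# Round half away from zero, the convention used for reported percentages
# (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Population (denominator-n) standard deviation; used for feature scaling so
# that a two-point training set standardizes to exactly +/-1.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

stop_field <- function(field, msg) {
  abort(paste0("invalid configuration field `", field, "`: ", msg),
        class = "cemarker_config_error")
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be in [0, 1]")
  }
  invisible(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    stop_field(field, "must be > 0")
  }
  invisible(x)
}

# Fisher-z confidence interval for a correlation coefficient.
fisher_z_ci <- function(r, n, conf = 0.95) {
  if (n <= 3 || abs(r) >= 1) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - conf) / 2)
  c(lower = tanh(z - q * se), upper = tanh(z + q * se))
}

geometric_mean <- function(x) {
  exp(mean(log(x)))
}
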