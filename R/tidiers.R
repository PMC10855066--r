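# broom-style tidiers for the fit objects

#' @exportS3Method generics::tidy
tidy.bh_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kapp", "ac", "intercept", "slope"),
    estimate = c(x$kapp, x$ac, x$intercept, x$slope),
    std.error = c(x$stderr_kapp, NA, summary(x$lm)$coefficients[, 2])
  )
}

#' @exportS3Method generics::glance
glance.bh_fit <- function(x, ...) {
  tibble::tibble(kapp = x$kapp, ac = x$ac, r.squared = x$r2,
                 stderr_kapp = x$stderr_kapp, nobs = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.quench_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ksv", "kq", "intercept"),
    estimate = c(x$ksv, x$kq, x$intercept),
    std.error = c(x$stderr_ksv, x$stderr_ksv / x$tau0,
                  summary(x$lm)$coefficients[1, 2])
  )
}

#' @exportS3Method generics::glance
glance.quench_fit <- function(x, ...) {
  tibble::tibble(ksv = x$ksv, kq = x$kq, tau0 = x$tau0,
                 intercept = x$intercept, r.squared = x$r2,
                 stderr_ksv = x$stderr_ksv,
                 temperature_k = x$temperature_k, nobs = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log_kb", "kb", "n"),
    estimate = c(x$log_kb, x$kb, x$n),
    std.error = c(x$stderr_log_kb, log(10) * x$kb * x$stderr_log_kb, x$stderr_n)
  )
}

#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble::tibble(log_kb = x$log_kb, kb = x$kb, n = x$n,
                 stderr_log_kb = x$stderr_log_kb, stderr_n = x$stderr_n,
                 r.squared = x$r2, temperature_k = x$temperature_k,
                 nobs = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.thermo_fit <- function(x, ...) {
  se <- summary(x$lm)$coefficients[, 2]
  tibble::tibble(
    term = c("dh", "ds"),
    estimate = c(x$dh, x$ds),
    std.error = c(R_GAS * se[[2]], R_GAS * se[[1]])
  )
}

#' @exportS3Method generics::glance
glance.thermo_fit <- function(x, ...) {
  tibble::tibble(dh = x$dh, ds = x$ds, r.squared = x$r2,
                 nobs = nrow(x$data))
}
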