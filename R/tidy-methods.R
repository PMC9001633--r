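# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bm_fit
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.bm_fit <- function(x, ...) {
  tibble::tibble(term = c("sigma2", "z0"),
                 estimate = c(x$sigma2, x$z0))
}

#' @rdname bm_fit
#' @export
glance.bm_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, z0 = x$z0, logLik = x$loglik,
                 AICc = x$aicc, nobs = x$n_tips)
}

#' @rdname mk_fit
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(term = "q", estimate = x$q)
}

#' @rdname mk_fit
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(q = x$q, k = x$k, logLik = x$loglik, model = x$model,
                 nobs = x$n_tips)
}

#' @rdname multirate_bm
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.multirate_bm <- function(x, ...) {
  tidyr::pivot_longer(x$rates, -"state", names_to = "term",
                      values_to = "estimate")
}

#' @rdname multirate_bm
#' @export
glance.multirate_bm <- function(x, ...) {
  tibble::tibble(n_maps = x$n_maps,
                 mean_weight_multi = x$mean_weight_multi,
                 sigma2_single = x$single$sigma2,
                 aicc_single = x$single$aicc,
                 mean_aicc_multi = mean(x$per_map$aicc_multi),
                 nobs = x$n_tips)
}

#' @rdname essim
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.essim_result <- function(x, ...) {
  tibble::tibble(term = "rho", estimate = x$rho, p.value = x$p_value)
}

#' @rdname essim
#' @export
glance.essim_result <- function(x, ...) {
  tibble::tibble(rho = x$rho, p.value = x$p_value, n_sim = x$n_sim,
                 sigma2 = x$sigma2, nobs = x$n_tips)
}

#' @rdname niche_pca
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.niche_pca <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 percent_variance = x$percent_variance,
                 broken_stick = x$broken_stick,
                 retained = seq_along(x$eigenvalues) <= x$n_retained)
}

#' @rdname niche_pca
#' @export
glance.niche_pca <- function(x, ...) {
  tibble::tibble(n_axes = length(x$eigenvalues),
                 n_retained = x$n_retained,
                 pc1_percent = x$percent_variance[1],
                 nobs = nrow(x$scores))
}

#' @rdname dtt
#' @param x A fitted object.
#' @param ... Unused.
#' @export
glance.dtt_result <- function(x, ...) {
  tibble::tibble(mdi = x$mdi, n_null = x$n_null, level = x$level)
}
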