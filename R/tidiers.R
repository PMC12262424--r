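# broom-style tidy()/glance() methods for fitted objects.

#' @export
tidy.intro_hmm <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("lambda_modern", "lambda_archaic", "stay_modern",
             "stay_archaic", "init_modern", "init_archaic"),
    estimate = c(p$lambda, diag(p$trans), p$init)
  )
}

#' @export
glance.intro_hmm <- function(x, ...) {
  tibble(loglik = x$loglik, iterations = x$iterations,
         converged = x$converged, degenerate = x$degenerate,
         n_windows = x$n_windows)
}

#' @export
tidy.selection_fit <- function(x, ...) x$params

#' @export
glance.selection_fit <- function(x, ...) {
  tibble(model = x$model, ll_alt = x$ll_alt, ll_null = x$ll_null,
         lrt_stat = x$lrt_stat, df = x$df, p_value = x$p_value)
}

#' @export
tidy.tmrca_grid <- function(x, ...) {
  nb <- length(x$bins)
  tibble(
    window = rep(seq_len(nrow(x$posterior)), each = nb),
    bin = rep(seq_len(nb), nrow(x$posterior)),
    tmrca = rep(x$bins, nrow(x$posterior)),
    posterior = as.numeric(t(x$posterior))
  )
}

#' @export
glance.tmrca_grid <- function(x, ...) {
  tibble(n_windows = nrow(x$posterior), n_bins = length(x$bins),
         loglik = x$loglik)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table))) |>
    rlang::set_names(c("introgression", "gene_proximity", "n"))
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, fisher_p = x$fisher_p,
         perm_p = x$perm_p, n_perm = x$n_perm, corrected = x$corrected)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble(statistic = x$statistic, n_rep = x$n_rep, n_redrawn = x$n_redrawn,
         median = stats::median(x$draws), q95 = quantile(x$draws, 0.95))
}

#' @export
tidy.mutation_rate_estimate <- function(x, ...) x$estimates

#' @export
glance.mutation_rate_estimate <- function(x, ...) {
  tibble(mean_mu = x$mean_mu, sd_mu = x$sd_mu,
         n_estimates = nrow(x$estimates), g = x$g)
}
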