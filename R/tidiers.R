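#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a discordance report
#'
#' One row per shared individual with per-category mismatch counts.
#'
#' @param x A `discordance_report` from [compare_matrices()].
#' @param ... Unused.
#' @return Tibble.
#' @method tidy discordance_report
#' @export
tidy.discordance_report <- function(x, ...) x$per_individual

#' One-row summary of a discordance report
#'
#' @inheritParams tidy.discordance_report
#' @return One-row tibble of means across individuals and the discordance
#'   rate.
#' @method glance discordance_report
#' @export
glance.discordance_report <- function(x, ...) x$summary

#' Tidy a bootstrapped pairwise-Fst estimate
#'
#' @param x A `pairwise_fst_ci` from [fst_bootstrap_ci()].
#' @param ... Unused.
#' @return Tibble with the point estimate and percentile interval.
#' @method tidy pairwise_fst_ci
#' @export
tidy.pairwise_fst_ci <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.pairwise_fst_ci
#' @method glance pairwise_fst_ci
#' @export
glance.pairwise_fst_ci <- function(x, ...) {
  tibble(theta = x$theta, ci_low = x$ci_low, ci_high = x$ci_high,
         n_loci = x$n_loci, n_boot = x$n_boot)
}

#' Tidy a primer screen report
#'
#' @param x A `screen_report` from [screen_panel()].
#' @param ... Unused.
#' @return Tibble with one row per (locus, failed rule); passing loci get a
#'   single row with `code = NA`.
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    codes <- x$codes[[i]]
    tibble(locus_id = x$locus_id[i], pass = x$pass[i],
           code = if (length(codes)) codes else NA_character_)
  })
}

#' @rdname tidy.screen_report
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  led <- attr(x, "ledger")
  tibble(candidates = led$candidates, retained = led$retained,
         removed = led$removed)
}
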