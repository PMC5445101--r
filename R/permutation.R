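#' Competitive-null engine configuration
#'
#' Defines how the null distribution of a set statistic is generated:
#' `"circular"` rotates the per-marker contributions around the circular
#' genome (preserving the local correlation structure among statistics) and
#' recomputes the statistic at the feature's original positions;
#' `"random_sets"` samples marker sets of the feature's size at random. The
#' `domain` restricts both rotation targets and sampled sets (for example to
#' genic markers only).
#'
#' @param mode `"circular"` or `"random_sets"`.
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical p-values.
#' @param domain optional integer vector of marker indices defining the null
#'   domain (default: all markers).
#' @param tie conservative `">="` (a permuted statistic equal to the observed
#'   one counts against the feature) or strict `">"`.
#' @param add_one use the add-one empirical p estimator
#'   `(count + 1) / (n_perm + 1)` so p is strictly positive; `FALSE` gives
#'   the raw proportion, which can be exactly zero.
#' @return an object of class `null_engine`.
#' @export
null_engine <- function(mode = c("circular", "random_sets"), n_perm = 10000,
                        seed = 1, domain = NULL, tie = c(">=", ">"),
                        add_one = TRUE) {
  mode <- match.arg(mode)
  tie <- match.arg(tie)
  if (n_perm < 100) stop("n_perm < 100 gives unstable p-values; refused")
  structure(list(mode = mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), domain = domain, tie = tie,
                 add_one = add_one), class = "null_engine")
}

#' Circular rotation of per-marker contributions
#'
#' Rotates a vector of per-marker values around the circular genome: element
#' `j` of the output is element `(j - offset) mod m` of the input, so markers
#' keep their positions and gain the statistic of the marker `offset` places
#' upstream.
#'
#' @param contribs numeric per-marker vector.
#' @param offset integer in `[0, m)`.
#' @return rotated vector of the same length.
#' @export
circular_permute <- function(contribs, offset) {
  m <- length(contribs)
  offset <- as.integer(offset) %% m
  if (offset == 0) return(contribs)
  contribs[((seq_len(m) - offset - 1) %% m) + 1]
}

# Feature sums of the rotated contribution vector for all m offsets at once,
# via circular cross-correlation in the Fourier domain. Exact up to FFT
# round-off (~1e-12 relative).
rotation_sums_fft <- function(contribs, feature_idx) {
  m <- length(contribs)
  ind <- numeric(m)
  ind[feature_idx] <- 1
  Re(stats::fft(Conj(stats::fft(contribs)) * stats::fft(ind),
                inverse = TRUE)) / m
}

rotation_sums_direct <- function(contribs, feature_idx, offsets) {
  m <- length(contribs)
  vapply(offsets, function(o) {
    sum(contribs[((feature_idx - o - 1) %% m) + 1])
  }, numeric(1))
}

#' Empirical p-value of a set statistic under the competitive null
#'
#' Generates `n_perm` null draws of the feature statistic — by circular
#' rotation of the per-marker contributions or by random marker-set sampling,
#' per the engine — and returns the one-tailed empirical p-value
#' `(#\{T_perm >= T_obs\} + 1) / (n_perm + 1)` (add-one estimator; the raw
#' proportion is available via the engine flag). The feature's marker indices
#' are fixed: only contributions move.
#'
#' @param observed observed statistic on the contribution-sum scale.
#' @param contribs per-marker contribution vector (see
#'   [per_marker_contributions()]).
#' @param feature integer marker indices of the feature, or a `feature_set`.
#' @param engine a [null_engine()].
#' @param scale multiplicative constant mapping contribution sums to the
#'   reported statistic (for example `1/(2 m_f)` for the score test); applied
#'   to both observed and null draws, so it does not affect p.
#' @param keep_null retain the null draws in the result.
#' @return list with `p_empirical`, `null_mean`, `null_var`, `n_perm`, and
#'   optionally `null_samples`.
#' @export
empirical_pvalue <- function(observed, contribs, feature, engine,
                             scale = 1, keep_null = FALSE) {
  f_idx <- feature_indices(feature)
  m <- length(contribs)
  stopifnot(all(f_idx >= 1), all(f_idx <= m))
  domain <- if (is.null(engine$domain)) seq_len(m) else engine$domain

  set.seed(engine$seed)
  if (engine$mode == "circular") {
    if (length(domain) < m) {
      # restrict the circle to the domain: rotate within domain positions
      sub <- contribs[domain]
      f_sub <- match(f_idx, domain)
      if (anyNA(f_sub)) stop("feature outside the null domain")
      offsets <- sample.int(length(domain), engine$n_perm, replace = TRUE)
      draws <- null_draws_circular(sub, f_sub, offsets)
    } else {
      offsets <- sample.int(m, engine$n_perm, replace = TRUE)
      draws <- null_draws_circular(contribs, f_idx, offsets)
    }
  } else {
    if (length(f_idx) > length(domain)) stop("feature larger than null domain")
    draws <- vapply(seq_len(engine$n_perm), function(i) {
      sum(contribs[domain[sample.int(length(domain), length(f_idx))]])
    }, numeric(1))
  }

  draws <- draws * scale
  tol <- 1e-9 * max(1, abs(observed), max(abs(draws)))
  hits <- if (engine$tie == ">=") sum(draws >= observed - tol)
          else sum(draws > observed + tol)
  p <- if (engine$add_one) (hits + 1) / (engine$n_perm + 1)
       else hits / engine$n_perm
  out <- list(p_empirical = p, null_mean = mean(draws),
              null_var = stats::var(draws), n_perm = engine$n_perm)
  if (keep_null) out$null_samples <- draws
  out
}

null_draws_circular <- function(contribs, f_idx, offsets) {
  m <- length(contribs)
  if (length(offsets) * length(f_idx) > 2e5 && m > 256) {
    S <- rotation_sums_fft(contribs, f_idx)
    S[(offsets %% m) + 1]
  } else {
    rotation_sums_direct(contribs, f_idx, offsets)
  }
}

#' Random marker-set null draws
#'
#' Draws the null distribution of a contribution-sum statistic by sampling
#' `m_f` markers without replacement from the null domain.
#'
#' @param contribs per-marker contribution vector.
#' @param m_f feature size.
#' @param engine a [null_engine()] (its `domain`, `n_perm`, `seed` are used).
#' @return numeric vector of `n_perm` null statistics.
#' @export
random_set_null <- function(contribs, m_f, engine) {
  domain <- if (is.null(engine$domain)) seq_along(contribs) else engine$domain
  if (m_f > length(domain)) stop("m_f exceeds the null domain")
  set.seed(engine$seed)
  vapply(seq_len(engine$n_perm), function(i) {
    sum(contribs[domain[sample.int(length(domain), m_f)]])
  }, numeric(1))
}
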