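# Sylvester construction: Hadamard matrix of order 2^k.
.hadamard <- function(order) {
  if (order < 1 || bitwAnd(order, order - 1L) != 0) {
    stop("Hadamard order must be a power of 2, got ", order)
  }
  H <- matrix(1, 1, 1)
  while (nrow(H) < order) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

# Collapse a design to pseudo-strata with exactly 2 PSUs each. Strata with
# more than 2 PSUs are split into consecutive pairs by PSU order; a leftover
# odd PSU is folded into the preceding pair's second half.
.pseudo_pairs <- function(stratum, psu) {
  out_stratum <- character(length(stratum))
  out_half <- integer(length(stratum))
  for (s in unique(stratum)) {
    in_s <- stratum == s
    psus <- sort(unique(psu[in_s]))
    if (length(psus) < 2) {
      stop("stratum '", s, "' has a single PSU; BRR needs two per stratum")
    }
    if (length(psus) > 2) {
      message("build_replicates: stratum '", s, "' has ", length(psus),
              " PSUs; splitting into pseudo-pairs by PSU order")
    }
    pair_idx <- ceiling(seq_along(psus) / 2)
    half <- 2L - seq_along(psus) %% 2L          # 1,2,1,2,...
    if (length(psus) %% 2 == 1 && length(psus) > 2) {
      pair_idx[length(psus)] <- pair_idx[length(psus)] - 1L
      half[length(psus)] <- 2L
    }
    for (j in seq_along(psus)) {
      sel <- in_s & psu == psus[j]
      out_stratum[sel] <- paste0(s, ".", pair_idx[j])
      out_half[sel] <- half[j]
    }
  }
  list(stratum = out_stratum, half = out_half)
}

#' Build Fay-adjusted BRR replicate weights
#'
#' Constructs balanced-repeated-replication replicate weights from masked
#' design variables (stratum, PSU) on a two-PSU-per-stratum design. In
#' replicate r, within each stratum, one PSU's respondents have their base
#' weight multiplied by `2 - fay_k` and the other PSU's by `fay_k`
#' (1.7 and 0.3 for the Fay coefficient 0.3; the classic BRR factors 2 and 0
#' at `fay_k = 0`). Half-sample selection follows the columns of a Sylvester
#' Hadamard matrix of the smallest power-of-two order with at least
#' `n_strata + 1` rows (the all-ones column is dropped so every stratum's
#' assignment column is balanced).
#'
#' @param respondents Respondent data.frame with `respondent_id`,
#'   `day1_weight`, `stratum`, `psu`.
#' @param fay_k Fay coefficient in `[0, 1)`; 0.3 by default.
#' @param hadamard_order Optional explicit order (power of 2, must exceed the
#'   number of pseudo-strata).
#' @return Object of class `"brr_weights"`: list with `base` (named vector),
#'   `reps` (matrix respondents x R), `fay_k`, `assignment` (strata x R sign
#'   matrix), `n_strata`, `n_psu`, `df` (= n_psu - n_strata), `R`.
#' @export
build_replicates <- function(respondents, fay_k = 0.3,
                             hadamard_order = NULL) {
  if (fay_k < 0 || fay_k >= 1) stop("fay_k must be in [0, 1)")
  pp <- .pseudo_pairs(respondents$stratum, respondents$psu)
  strata <- sort(unique(pp$stratum))
  S <- length(strata)
  n_psu <- 2L * S
  if (is.null(hadamard_order)) {
    hadamard_order <- 2^ceiling(log2(S + 1))
  }
  if (hadamard_order < S + 1) {
    stop("hadamard_order must be at least n_strata + 1 = ", S + 1)
  }
  H <- .hadamard(hadamard_order)
  assignment <- H[, seq_len(S) + 1L, drop = FALSE]  # drop all-ones column
  R <- nrow(assignment)
  base <- setNames(respondents$day1_weight,
                   as.character(respondents$respondent_id))
  stratum_idx <- match(pp$stratum, strata)
  first_half <- pp$half == 1L
  reps <- matrix(0, length(base), R,
                 dimnames = list(names(base), paste0("rep", seq_len(R))))
  for (r in seq_len(R)) {
    selected_first <- assignment[r, stratum_idx] == 1
    factor_r <- ifelse(selected_first == first_half, 2 - fay_k, fay_k)
    reps[, r] <- base * factor_r
  }
  structure(list(base = base, reps = reps, fay_k = fay_k,
                 assignment = t(assignment), n_strata = S, n_psu = n_psu,
                 df = n_psu - S, R = R),
            class = "brr_weights")
}

#' @export
print.brr_weights <- function(x, ...) {
  cat("BRR replicate weights: ", length(x$base), " respondents, ",
      x$n_strata, " strata (", x$n_psu, " PSUs), R = ", x$R,
      ", Fay k = ", x$fay_k, "\n", sep = "")
  invisible(x)
}

#' BRR standard error of an arbitrary statistic
#'
#' Evaluates `statistic_fn(data, w)` under the base weights and under each
#' Fay-adjusted replicate weight vector, and returns
#' `sqrt(sum((theta_r - theta_hat)^2) / (R * (1 - fay_k)^2))`. The statistic
#' may be vector-valued; the result then has one SE per element. The result
#' does not depend on the order of the replicates.
#'
#' @param statistic_fn Function of `(data, weights)` returning a numeric
#'   scalar or vector.
#' @param data Passed through to `statistic_fn`.
#' @param replicates `"brr_weights"` object.
#' @return Standard error(s), same shape/names as the statistic.
#' @export
brr_se <- function(statistic_fn, data, replicates) {
  theta_hat <- statistic_fn(data, replicates$base)
  thetas <- vapply(seq_len(replicates$R), function(r) {
    res <- tryCatch(statistic_fn(data, replicates$reps[, r]),
                    error = function(e) {
                      stop("statistic failed on replicate ", r, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    as.numeric(res)
  }, numeric(length(theta_hat)))
  thetas <- matrix(thetas, nrow = length(theta_hat))
  dev2 <- (thetas - as.numeric(theta_hat))^2
  se <- sqrt(rowSums(dev2) / (replicates$R * (1 - replicates$fay_k)^2))
  setNames(se, names(theta_hat))
}

#' Pairwise outlet contrast with BRR inference
#'
#' Tests the difference between two outlets' group statistics (typically
#' HEI-2015 total or component scores). The difference is formed within each
#' replicate, its BRR standard error computed, and a two-sided t test
#' performed with `df = n_psu - n_strata` degrees of freedom. Differences
#' with p below 0.05 are flagged significant.
#'
#' @param scores_fn Function of `(data, weights)` returning a named numeric
#'   vector of per-outlet statistics containing both elements of `pair`.
#' @param data Passed through to `scores_fn`.
#' @param replicates `"brr_weights"` object.
#' @param pair Character vector of the two outlet names, difference taken as
#'   first minus second.
#' @return Object of class `"hei_contrast"`: estimate, SE, t statistic, df,
#'   p value, pair, significant flag.
#' @export
pairwise_contrast <- function(scores_fn, data, replicates, pair) {
  if (length(pair) != 2) stop("pair must name exactly two outlets")
  diff_fn <- function(d, w) {
    s <- scores_fn(d, w)
    if (!all(pair %in% names(s))) {
      stop("scores_fn must return elements named ",
           paste(pair, collapse = " and "))
    }
    unname(s[[pair[1]]] - s[[pair[2]]])
  }
  estimate <- diff_fn(data, replicates$base)
  se <- unname(brr_se(diff_fn, data, replicates))
  df <- replicates$df
  if (se == 0) {
    statistic <- if (estimate == 0) 0 else Inf * sign(estimate)
    p <- if (estimate == 0) 1 else 0
  } else {
    statistic <- estimate / se
    p <- 2 * pt(-abs(statistic), df)
  }
  structure(list(pair = pair, estimate = estimate, se = se,
                 statistic = statistic, df = df, p_value = p,
                 significant = p < 0.05),
            class = "hei_contrast")
}

#' @export
print.hei_contrast <- function(x, ...) {
  cat(sprintf("Contrast %s - %s: %.3f (BRR SE %.3f), t = %.3f on %d df, p = %.4g%s\n",
              x$pair[1], x$pair[2], x$estimate, x$se, x$statistic, x$df,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Linear trend in a group statistic across survey cycles
#'
#' Regresses the cycle-level statistic (e.g. an outlet's population-ratio
#' HEI-2015 total) on the cycle index 0, 1, ... via ordinary least squares,
#' using each cycle's own replicate set: replicate r's slope is recomputed
#' with replicate-r weights in every cycle, and the slope's standard error
#' follows the BRR formula. Requires at least three cycles and the same
#' number of replicates per cycle (use a common `hadamard_order`).
#'
#' @param statistic_fn Function of `(data, weights)` returning a scalar.
#' @param data_by_cycle Named list of per-cycle data, in cycle order.
#' @param replicates_by_cycle List of `"brr_weights"` objects, parallel to
#'   `data_by_cycle`.
#' @return Object of class `"hei_trend"`: slope, SE, t, df, p, per-cycle
#'   estimates.
#' @export
trend_test <- function(statistic_fn, data_by_cycle, replicates_by_cycle) {
  C <- length(data_by_cycle)
  if (C < 3) stop("trend test needs at least 3 cycles, got ", C)
  if (length(replicates_by_cycle) != C) {
    stop("replicates_by_cycle must parallel data_by_cycle")
  }
  Rs <- vapply(replicates_by_cycle, function(x) x$R, numeric(1))
  if (length(unique(Rs)) != 1) {
    stop("all cycles must share the same replicate count; got ",
         paste(Rs, collapse = ", "))
  }
  R <- Rs[[1]]
  k <- replicates_by_cycle[[1]]$fay_k
  x <- seq_len(C) - 1
  slope_of <- function(y) {
    xc <- x - mean(x)
    sum(xc * (y - mean(y))) / sum(xc^2)
  }
  y_hat <- vapply(seq_len(C), function(cc) {
    statistic_fn(data_by_cycle[[cc]], replicates_by_cycle[[cc]]$base)
  }, numeric(1))
  slope_hat <- slope_of(y_hat)
  slopes_r <- vapply(seq_len(R), function(r) {
    y_r <- vapply(seq_len(C), function(cc) {
      statistic_fn(data_by_cycle[[cc]], replicates_by_cycle[[cc]]$reps[, r])
    }, numeric(1))
    slope_of(y_r)
  }, numeric(1))
  se <- sqrt(sum((slopes_r - slope_hat)^2) / (R * (1 - k)^2))
  df <- sum(vapply(replicates_by_cycle, function(z) z$df, numeric(1)))
  if (se == 0) {
    statistic <- if (slope_hat == 0) 0 else Inf * sign(slope_hat)
    p <- if (slope_hat == 0) 1 else 0
  } else {
    statistic <- slope_hat / se
    p <- 2 * pt(-abs(statistic), df)
  }
  structure(list(slope = slope_hat, se = se, statistic = statistic, df = df,
                 p_value = p, estimates = setNames(y_hat,
                                                   names(data_by_cycle)),
                 significant = p < 0.05),
            class = "hei_trend")
}

#' @export
print.hei_trend <- function(x, ...) {
  cat(sprintf("Linear trend: slope %.4f per cycle (BRR SE %.4f), t = %.3f on %d df, p = %.4g%s\n",
              x$slope, x$se, x$statistic, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
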