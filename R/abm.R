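# Agent-based Monte-Carlo oracle. The behavioural rules are simulated
# directly: M agents of fixed type are paired by a uniform random
# perfect matching every round; cooperators always play C, defectors
# always play D, and a discriminator copies its current partner's
# publicly recorded action from the previous round (cooperating with
# probability p in round 1, when no record exists). Type frequencies do
# not evolve within a run -- frequency dynamics belong to the replicator
# module; this module checks the mean-field payoff algebra empirically.

#' Configuration for the agent-based simulation
#'
#' @param M Number of agents; must be even so every round admits a
#'   perfect matching.
#' @param seed Master random seed; it spawns one sub-seed per replicate,
#'   all recorded in the result.
#' @param replicates Number of independent replicate runs (>= 1).
#' @return An object of class `abm_config`.
#' @export
abm_config <- function(M, seed, replicates = 1) {
  if (M < 2 || M != round(M) || M %% 2 != 0)
    stop("agent count M must be a positive even integer", call. = FALSE)
  if (replicates < 1 || replicates != round(replicates))
    stop("'replicates' must be a positive integer", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  structure(list(M = as.integer(M), seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "abm_config")
}

# Largest-remainder apportionment of M agents to the three types.
.type_counts <- function(M, x) {
  base <- floor(M * x)
  rem <- M * x - base
  k <- M - sum(base)
  if (k > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# One replicate. types: 1 = cooperator, 2 = defector, 3 = discriminator.
# Returns per-type per-capita cumulative payoffs and the per-round
# fraction of agents acting cooperatively.
.abm_replicate <- function(params, types, N) {
  M <- length(types)
  piv <- params$pi; cc <- params$c; th <- params$theta
  payoff <- numeric(M)
  coop_frac <- numeric(N)
  is_disc <- types == 3L
  last_act <- logical(M)
  for (n in seq_len(N)) {
    perm <- sample.int(M)
    partner <- integer(M)
    i <- perm[seq(1, M, by = 2)]
    j <- perm[seq(2, M, by = 2)]
    partner[i] <- j
    partner[j] <- i
    act <- types == 1L
    if (n == 1L) {
      # no reputation record yet: discriminators cooperate w.p. p
      act[is_disc] <- stats::runif(sum(is_disc)) < params$p
    } else {
      # discriminator copies its current partner's recorded action
      act[is_disc] <- last_act[partner][is_disc]
    }
    mine <- act
    theirs <- act[partner]
    payoff <- payoff +
      ifelse(mine & theirs, piv - cc,
             ifelse(mine & !theirs, th * piv - cc,
                    ifelse(!mine & theirs, th * piv, 0)))
    coop_frac[n] <- mean(act)
    last_act <- act
  }
  by_type <- vapply(1:3, function(k) {
    if (any(types == k)) mean(payoff[types == k]) else NA_real_
  }, numeric(1))
  list(payoff_by_type = by_type, coop_frac = coop_frac,
       total_payoff = sum(payoff))
}

#' Run the agent-based simulation
#'
#' Simulates `config$replicates` independent runs of the N-round game at
#' a fixed population composition and aggregates per-capita cumulative
#' payoffs by type and per-round cooperation fractions, with
#' Monte-Carlo standard errors across replicates. Agent counts are the
#' largest-remainder rounding of `M * x_i`; the realised fractions are
#' recorded in the result and should be used for mean-field comparisons.
#'
#' @inheritParams coop_fraction
#' @param config An [abm_config()].
#' @return An object of class `abm_result`: `mean_payoff_by_type`
#'   (named: cooperator, defector, discriminator; `NA` for
#'   unrepresented types), `coop_fraction_by_round` (length `N`),
#'   `standard_errors` (list `payoff`, `coop`), `counts`,
#'   `realized_state`, `replicate_seeds`, and the per-replicate matrices
#'   under `per_replicate`.
#' @examples
#' params <- game_parameters(10, 1e6, 0.5e6, 0.75, 0.5)
#' res <- run_abm(params, population_state(0.3, 0.3, 0.4),
#'                abm_config(M = 200, seed = 1, replicates = 4))
#' res$mean_payoff_by_type
#' @export
run_abm <- function(params, state, config) {
  .check_params(params)
  if (!inherits(state, "population_state"))
    state <- population_state(state[[1]], state[[2]], state[[3]])
  if (!inherits(config, "abm_config"))
    stop("'config' must be created by abm_config()", call. = FALSE)
  x <- unclass(state)
  counts <- .type_counts(config$M, x)
  for (k in which(x > 0 & counts == 0)) {
    warning(sprintf(
      "type %d has positive fraction %.3g but no agents at M = %d",
      k, x[k], config$M), call. = FALSE)
  }
  types <- rep.int(1:3, counts)
  N <- params$N
  R <- config$replicates

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)

  pay_mat <- matrix(NA_real_, nrow = R, ncol = 3)
  coop_mat <- matrix(NA_real_, nrow = R, ncol = N)
  totals <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    one <- .abm_replicate(params, types, N)
    pay_mat[r, ] <- one$payoff_by_type
    coop_mat[r, ] <- one$coop_frac
    totals[r] <- one$total_payoff
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  mean_pay <- colMeans(pay_mat)
  names(mean_pay) <- c("cooperator", "defector", "discriminator")
  pay_se <- apply(pay_mat, 2, se)
  names(pay_se) <- names(mean_pay)
  structure(
    list(mean_payoff_by_type = mean_pay,
         coop_fraction_by_round = colMeans(coop_mat),
         standard_errors = list(payoff = pay_se,
                                coop = apply(coop_mat, 2, se)),
         counts = counts,
         realized_state = counts / config$M,
         total_payoff_per_replicate = totals,
         per_replicate = list(payoff = pay_mat, coop = coop_mat),
         params = params,
         state = unclass(state),
         config = config,
         replicate_seeds = rep_seeds),
    class = "abm_result")
}

#' @export
print.abm_result <- function(x, ...) {
  cat(sprintf("ABM result: M = %d agents, %d rounds, %d replicates (seed %d)\n",
              x$config$M, x$params$N, x$config$replicates, x$config$seed))
  cat(sprintf("  counts (coop, def, disc): %s\n",
              paste(x$counts, collapse = ", ")))
  for (k in seq_along(x$mean_payoff_by_type)) {
    cat(sprintf("  %-13s payoff %.6g (se %.3g)\n",
                names(x$mean_payoff_by_type)[k],
                x$mean_payoff_by_type[k], x$standard_errors$payoff[k]))
  }
  cat(sprintf("  final-round cooperation fraction %.4f\n",
              x$coop_fraction_by_round[x$params$N]))
  invisible(x)
}

#' Compare agent-based results with the mean-field formulas
#'
#' Computes z-scores (empirical minus analytic, over the Monte-Carlo
#' standard error) for the cooperator, defector, and discriminator
#' cumulative payoffs against R1, R2, R3, and for every per-round
#' cooperation fraction against \eqn{g_n}. Analytic values are
#' evaluated at the realised (integer-count) population fractions. The
#' cooperator, defector, and \eqn{g_n} expectations are exact under
#' random matching, so those blocks carry `agreement_expected = TRUE`;
#' the discriminator's mean-field payoff neglects the correlation
#' between a partner's type and that partner's recorded action (a
#' defector's record is always D from round 2 on), so its gap is
#' reported without asserting agreement.
#'
#' @param result A [run_abm()] result.
#' @inheritParams coop_fraction
#' @return An object of class `abm_comparison`: one block per payoff
#'   comparison plus a `g_by_round` block, each with `empirical`,
#'   `analytic`, `se`, `z`, and `agreement_expected`.
#' @export
compare_abm_analytic <- function(result, params, state) {
  if (!inherits(result, "abm_result"))
    stop("'result' must be a run_abm() result", call. = FALSE)
  .check_params(params)
  if (!inherits(state, "population_state"))
    state <- population_state(state[[1]], state[[2]], state[[3]])
  same_params <- isTRUE(all.equal(
    unclass(result$params)[c("N", "pi", "c", "theta", "p")],
    unclass(params)[c("N", "pi", "c", "theta", "p")], tolerance = 0))
  if (!same_params || max(abs(result$state - unclass(state))) > 1e-12)
    stop("'result' was produced under different parameters or state",
         call. = FALSE)

  x1 <- result$realized_state[1]
  x3 <- result$realized_state[3]
  totals <- .total_x13(params, x1, x3)
  zscore <- function(emp, ana, se) {
    d <- emp - ana
    ifelse(se == 0, ifelse(abs(d) < 1e-9 * max(1, abs(ana)), 0, Inf), d / se)
  }
  block <- function(k, ana, expected) {
    emp <- unname(result$mean_payoff_by_type[k])
    se <- unname(result$standard_errors$payoff[k])
    list(empirical = emp, analytic = unname(ana), se = se,
         z = zscore(emp, ana, se), agreement_expected = expected)
  }
  n <- seq_len(params$N)
  g_ana <- if (.near_pole(x3)) .g_seq(params, x1, x3, params$N)
           else {
             a <- x1 / (1 - x3)
             a + x3^n * (params$p - a)
           }
  g_emp <- result$coop_fraction_by_round
  g_se <- result$standard_errors$coop
  structure(
    list(cooperator = block(1, totals["r1"], TRUE),
         defector = block(2, totals["r2"], TRUE),
         discriminator = block(3, totals["r3"], FALSE),
         g_by_round = list(empirical = g_emp, analytic = unname(g_ana),
                           se = g_se, z = zscore(g_emp, g_ana, g_se),
                           agreement_expected = TRUE),
         params = params,
         state = unclass(state)),
    class = "abm_comparison")
}

#' @export
print.abm_comparison <- function(x, ...) {
  cat("ABM vs mean-field comparison\n")
  for (nm in c("cooperator", "defector", "discriminator")) {
    b <- x[[nm]]
    cat(sprintf(
      "  %-13s empirical %.6g vs analytic %.6g  (z = %+.2f)%s\n",
      nm, b$empirical, b$analytic, b$z,
      if (b$agreement_expected) "" else "  [gap reported, not asserted]"))
  }
  gz <- x$g_by_round$z[is.finite(x$g_by_round$z)]
  cat(sprintf("  g_n by round: max |z| = %.2f over %d rounds\n",
              if (length(gz)) max(abs(gz)) else 0,
              length(x$g_by_round$z)))
  invisible(x)
}

#' Write an ABM result to CSV and JSON
#'
#' The CSV holds the per-round empirical cooperation fractions and
#' their standard errors; the JSON holds the payoff summary, the
#' configuration, and all replicate seeds.
#'
#' @param result A [run_abm()] result.
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path (default: `csv_path` with a
#'   `.json` extension).
#' @return Invisibly, the paths written.
#' @export
write_abm_result <- function(result, csv_path,
                             json_path = paste0(
                               tools::file_path_sans_ext(csv_path), ".json")) {
  if (!inherits(result, "abm_result"))
    stop("'result' must be a run_abm() result", call. = FALSE)
  df <- data.frame(round = seq_along(result$coop_fraction_by_round),
                   coop_fraction = result$coop_fraction_by_round,
                   se = result$standard_errors$coop)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  out <- list(parameters = unclass(result$params),
              state = result$state,
              counts = result$counts,
              config = unclass(result$config),
              replicate_seeds = result$replicate_seeds,
              mean_payoff_by_type = as.list(result$mean_payoff_by_type),
              payoff_se = as.list(result$standard_errors$payoff))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
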