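#' Coarse ground-truth class of stream droplets
#'
#' @param stream A `droplet_stream`.
#' @return Character vector: `"empty"`, `"single"` or `"multi"` by cell
#'   count (viability does not change what the droplet truly contains).
#' @export
stream_true_class <- function(stream) {
  ifelse(stream$cell_count == 0, "empty",
         ifelse(stream$cell_count == 1, "single", "multi"))
}

#' Virtually sort a screened droplet stream
#'
#' Routes every droplet: to the target outlet iff a trigger fired for its
#' event and the acoustic deflection is feasible; otherwise it follows the
#' flow to the waste outlet by default. Droplets whose event was never
#' detected stay on the default path.
#'
#' @param stream The ground-truth `droplet_stream`.
#' @param events Screened events carrying `droplet_id`, `label`,
#'   `triggered` (from [screen_trace()] + [schedule_triggers()]).
#' @param deflectable Logical scalar or per-event vector: is the acoustic
#'   push sufficient ([deflection_feasible()])? Default `TRUE`.
#' @return A `sort_outcome` list: `destinations` data.frame (droplet_id,
#'   true_class, label, destination), plus the [sort_metrics()] summary.
#' @export
virtual_sort <- function(stream, events, deflectable = TRUE) {
  stopifnot(inherits(stream, "droplet_stream"))
  if (nrow(events) > 0) {
    if (!all(c("droplet_id", "label", "triggered") %in% names(events)))
      stop("events must carry droplet_id, label and triggered")
    bad <- setdiff(stats::na.omit(events$droplet_id), stream$droplet_id)
    if (length(bad) > 0)
      stop("unmatched event droplet ids: ", paste(bad, collapse = ", "))
  }
  truth <- stream_true_class(stream)
  dest <- rep("waste", nrow(stream))
  label <- rep(NA_character_, nrow(stream))
  if (nrow(events) > 0) {
    ok <- !is.na(events$droplet_id)
    defl <- if (length(deflectable) == 1) rep(deflectable, nrow(events))
            else deflectable
    i <- match(events$droplet_id[ok], stream$droplet_id)
    label[i] <- events$label[ok]
    to_target <- events$triggered[ok] & defl[ok]
    dest[i[to_target]] <- "target"
  }
  destinations <- data.frame(droplet_id = stream$droplet_id,
                             true_class = truth,
                             label = label,
                             destination = dest)
  duration_s <- max(stream$arrival_time_s) - min(stream$arrival_time_s)
  out <- structure(list(destinations = destinations,
                        duration_s = duration_s),
                   class = "sort_outcome")
  out$metrics <- sort_metrics(out)
  out
}

#' Sorting performance metrics
#'
#' Composition is reported on two bases: among all droplets and among
#' cell-containing droplets only. Purity is the target-class fraction in
#' the target outlet; recovery divides by all true target-class droplets
#' that entered the sorter during the run (detection failures count
#' against recovery); enrichment is the post/pre target-class fraction
#' ratio.
#'
#' @param outcome A `sort_outcome`.
#' @param target_class True class counted as the sorting goal (default
#'   `"single"`).
#' @return List with pre/post compositions (percent, both bases), purity,
#'   recovery, enrichment_fold, per-class rejection rates (percent of the
#'   class sent to waste), counts, throughput (target-outlet droplets per
#'   second) and duration.
#' @export
sort_metrics <- function(outcome, target_class = "single") {
  d <- outcome$destinations
  classes <- c("empty", "single", "multi")
  pre <- table(factor(d$true_class, classes))
  in_target <- d$destination == "target"
  post <- table(factor(d$true_class[in_target], classes))
  comp <- function(x) {
    tot <- sum(x)
    if (tot == 0) stats::setNames(rep(NA_real_, length(x)), names(x))
    else 100 * x / tot
  }
  cellsel <- function(x) x[c("single", "multi")]
  n_target_out <- sum(in_target)
  purity <- if (n_target_out == 0) NA_real_
            else 100 * post[[target_class]] / n_target_out
  recovery <- if (pre[[target_class]] == 0) NA_real_
              else 100 * post[[target_class]] / pre[[target_class]]
  pre_frac <- comp(pre)[[target_class]]
  post_frac <- comp(post)[[target_class]]
  enrich <- if (isTRUE(pre_frac > 0)) post_frac / pre_frac else NA_real_
  rejection <- 100 * (1 - as.numeric(post) / pmax(as.numeric(pre), 1))
  names(rejection) <- classes
  list(target_class = target_class,
       counts = list(total = nrow(d), target_outlet = n_target_out,
                     waste_outlet = sum(!in_target)),
       pre_composition_pct = comp(pre),
       post_composition_pct = comp(post),
       pre_composition_cells_pct = comp(cellsel(pre)),
       post_composition_cells_pct = comp(cellsel(post)),
       purity_pct = purity,
       recovery_pct = recovery,
       enrichment_fold = unname(enrich),
       rejection_pct = rejection,
       throughput_hz = if (outcome$duration_s > 0)
         n_target_out / outcome$duration_s else NA_real_,
       duration_s = outcome$duration_s)
}

#' Enrichment fold from printed compositions
#'
#' @param pre_pct,post_pct Target-class percentages before and after
#'   sorting.
#' @return Fold change `post/pre`.
#' @examples
#' enrichment_fold(5.2, 81.7)  # ~15.7, i.e. about 16-fold
#' @export
enrichment_fold <- function(pre_pct, post_pct) {
  stopifnot(pre_pct > 0, post_pct >= 0)
  post_pct / pre_pct
}

#' Throughput fold change between two collections
#'
#' @param counts Collected single-cell droplet counts (length 2,
#'   high-loading first).
#' @param duration_s Collection durations in seconds (length 2).
#' @return Ratio of collection rates (first over second).
#' @examples
#' throughput_fold(c(28948, 19875), c(30, 180) * 60)  # ~8.7, rounds to 9
#' @export
throughput_fold <- function(counts, duration_s) {
  stopifnot(length(counts) == 2, length(duration_s) == 2,
            all(duration_s > 0))
  (counts[1] / duration_s[1]) / (counts[2] / duration_s[2])
}

#' Theoretical and simulated throughput comparison across loadings
#'
#' For each \eqn{\lambda}: the theoretical sorted single-cell rate under
#' the sorter cap, the expected collection over the stated duration, and
#' a seeded Monte-Carlo collection count (Poisson thinning of the droplet
#' stream at the cap rate).
#'
#' @param lam Vector of Poisson means.
#' @param duration_s Collection durations (recycled).
#' @param max_sort_rate_hz Sorter rate cap (default 200).
#' @param seed Seed for the simulated counts (default NULL: expectation
#'   only).
#' @return data.frame with `lam`, `duration_s`, `rate_hz`,
#'   `expected_count`, and `simulated_count` when seeded. Fold changes of
#'   successive rows are in `attr(, "fold_vs_last")`.
#' @export
throughput_comparison <- function(lam, duration_s,
                                  max_sort_rate_hz = 200, seed = NULL) {
  stopifnot(all(lam > 0))
  duration_s <- rep_len(duration_s, length(lam))
  rate <- theoretical_sorted_throughput(lam, max_sort_rate_hz)
  expected <- rate * duration_s
  sim <- rep(NA_real_, length(lam))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    n_droplets <- round(max_sort_rate_hz * duration_s)
    sim <- vapply(seq_along(lam), function(i) {
      sum(stats::rpois(n_droplets[i], lam[i]) == 1)
    }, 0)
  }
  out <- data.frame(lam = lam, duration_s = duration_s, rate_hz = rate,
                    expected_count = expected, simulated_count = sim)
  attr(out, "fold_vs_last") <- (out$rate_hz / out$rate_hz[nrow(out)])
  out
}

#' Purity/recovery trade-off over a gate grid
#'
#' Sweeps single-cell gate intervals over a labelled amplitude sample and
#' reports purity and recovery for each, plus the Pareto frontier.
#'
#' @param amplitudes Peak amplitudes.
#' @param true_class Coarse true classes (`"empty"|"single"|"multi"`).
#' @param lower_grid,upper_grid Candidate gate bounds; all pairs with
#'   `lower < upper` are evaluated.
#' @return data.frame `lower_uA`, `upper_uA`, `purity_pct`,
#'   `recovery_pct`, `accepted`, `pareto` (logical).
#' @export
gate_tradeoff <- function(amplitudes, true_class, lower_grid, upper_grid) {
  stopifnot(length(amplitudes) == length(true_class),
            length(unique(true_class)) >= 1)
  grid <- expand.grid(lower_uA = lower_grid, upper_uA = upper_grid)
  grid <- grid[grid$lower_uA < grid$upper_uA, , drop = FALSE]
  n_single <- sum(true_class == "single")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    inside <- amplitudes >= grid$lower_uA[i] & amplitudes < grid$upper_uA[i]
    acc <- sum(inside)
    tp <- sum(inside & true_class == "single")
    data.frame(lower_uA = grid$lower_uA[i], upper_uA = grid$upper_uA[i],
               purity_pct = if (acc > 0) 100 * tp / acc else NA_real_,
               recovery_pct = if (n_single > 0) 100 * tp / n_single
                              else NA_real_,
               accepted = acc)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$purity_pct)
  pareto <- rep(FALSE, nrow(out))
  idx <- which(ok)
  for (i in idx) {
    dominated <- any(out$purity_pct[idx] >= out$purity_pct[i] &
                     out$recovery_pct[idx] >= out$recovery_pct[i] &
                     (out$purity_pct[idx] > out$purity_pct[i] |
                      out$recovery_pct[idx] > out$recovery_pct[i]))
    pareto[i] <- !dominated
  }
  out$pareto <- pareto
  out
}
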