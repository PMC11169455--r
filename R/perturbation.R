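#' Define an enzyme perturbation scenario
#'
#' Overexpression is modelled purely as multiplicative scaling of Vmax
#' (Vmax = kcat [E], so an f-fold abundance change is an f-fold Vmax change);
#' Km values are untouched. Factor 0 is a knockout. For mass-action steps
#' attributed to an enzyme, the rate constant k is scaled instead. All
#' reactions sharing an enzyme label (e.g. the two active sites of
#' bifunctional TH1) are scaled together.
#'
#' @param fold_changes Named numeric vector, enzyme label -> factor (>= 0).
#' @param name Scenario label (default built from the factors).
#' @param target_metabolite Metabolite whose trajectory the scan reports
#'   (default `"TMP"`).
#' @return An object of class `thiamsim_scenario`.
#' @export
perturbation_scenario <- function(fold_changes, name = NULL,
                                  target_metabolite = "TMP") {
  fold_changes <- unlist(fold_changes)
  if (length(fold_changes) > 0 &&
      (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes)))))
    stop("fold_changes must be a named vector (enzyme label -> factor)")
  if (any(fold_changes < 0)) stop("fold factors must be >= 0")
  if (is.null(name))
    name <- if (length(fold_changes) == 0L) "baseline" else
      paste(sprintf("%s x%g", names(fold_changes), fold_changes), collapse = ", ")
  structure(list(name = name, fold_changes = fold_changes,
                 target_metabolite = target_metabolite),
            class = "thiamsim_scenario")
}

#' Apply a perturbation scenario to a model
#'
#' Returns a new model; the input is not mutated. Every reaction whose enzyme
#' label appears in the scenario has its Vmax (MM laws) or k (mass-action /
#' constant-flux steps) multiplied by the factor; all other parameters are
#' untouched.
#'
#' @param model A `thiamsim_model`.
#' @param scenario A [perturbation_scenario()].
#' @return A new `thiamsim_model`.
#' @export
apply_perturbation <- function(model, scenario) {
  fc <- scenario$fold_changes
  unknown <- setdiff(names(fc), enzyme_labels(model))
  if (length(unknown) > 0L)
    stop("unknown enzyme label(s): ", paste(unknown, collapse = ", "),
         "; valid labels: ", paste(enzyme_labels(model), collapse = ", "))
  model$reactions <- lapply(model$reactions, function(r) {
    if (!r$enzyme %in% names(fc) || is.null(r$law)) return(r)
    f <- fc[[r$enzyme]]
    if (r$law$law_type %in% c("MM1", "MM2")) r$law$vmax <- r$law$vmax * f
    else r$law$k <- r$law$k * f
    r
  })
  model
}

#' Enumerate the standard overexpression scenarios
#'
#' By default: each enzyme alone plus the all-enzymes combination (the
#' singles-plus-triple design used to compare biofortification strategies).
#' With `powerset = TRUE`, every non-empty subset (2^n - 1 scenarios,
#' refused for n > 12).
#'
#' @param model A `thiamsim_model`.
#' @param enzymes Character vector of enzyme labels to perturb.
#' @param fold Common fold factor (default 100).
#' @param target_metabolite Reported metabolite (default `"TMP"`).
#' @param powerset Enumerate the full power set instead.
#' @return List of [perturbation_scenario()] objects.
#' @export
enumerate_standard_scenarios <- function(model, enzymes, fold = 100,
                                         target_metabolite = "TMP",
                                         powerset = FALSE) {
  unknown <- setdiff(enzymes, enzyme_labels(model))
  if (length(unknown) > 0L)
    stop("unknown enzyme label(s): ", paste(unknown, collapse = ", "))
  subsets <- if (powerset) {
    if (length(enzymes) > 12L)
      stop("power-set enumeration refused for more than 12 enzymes (",
           length(enzymes), " requested); pass an explicit scenario list instead")
    unlist(lapply(seq_along(enzymes), function(k)
      utils::combn(enzymes, k, simplify = FALSE)), recursive = FALSE)
  } else if (length(enzymes) == 1L) {
    list(enzymes)
  } else {
    c(as.list(enzymes), list(enzymes))
  }
  lapply(subsets, function(s)
    perturbation_scenario(stats::setNames(rep(fold, length(s)), s),
                          target_metabolite = target_metabolite))
}

#' Run an overexpression/knockout scan
#'
#' Simulates the baseline model plus every scenario and reports, for the
#' target metabolite of each scenario: final concentration, plateau flag and
#' value, peak time and value, area under the curve, and the ratio of the
#' final concentration to baseline. Scenarios are ranked by the chosen
#' criterion (the baseline row is always included and participates in the
#' ranking). Per-scenario simulation failures are flagged in the report, not
#' propagated.
#'
#' @param model A `thiamsim_model` (fully parameterised).
#' @param scenarios List of [perturbation_scenario()] objects.
#' @param config A [simulation_config()].
#' @param rank_by Ranking criterion: `"final"` (default; sustained
#'   concentration), `"peak"`, or `"auc"`.
#' @return A `thiamsim_scan` list: `report` (data.frame, ranked), and
#'   `trajectories` (named list of `thiamsim_timecourse`, `NULL` for failed
#'   rows).
#' @export
run_scan <- function(model, scenarios, config = simulation_config(),
                     rank_by = c("final", "peak", "auc")) {
  rank_by <- match.arg(rank_by)
  target0 <- if (length(scenarios) > 0L) scenarios[[1L]]$target_metabolite else "TMP"
  all <- c(list(perturbation_scenario(numeric(), name = "baseline",
                                      target_metabolite = target0)),
           scenarios)
  rows <- list(); trajs <- list()
  for (sc in all) {
    res <- tryCatch({
      r <- simulate_pathway(apply_perturbation(model, sc), config)
      .series(r, sc$target_metabolite)  # fail early on unknown targets
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[sc$name]] <- data.frame(
        scenario = sc$name, target = sc$target_metabolite, ok = FALSE,
        final = NA_real_, plateau = NA, plateau_value = NA_real_,
        t_peak = NA_real_, v_peak = NA_real_, auc = NA_real_,
        fold_vs_baseline = NA_real_,
        error = conditionMessage(res), stringsAsFactors = FALSE)
      trajs[sc$name] <- list(NULL)
      next
    }
    s <- .series(res, sc$target_metabolite)
    pl <- detect_plateau(res, sc$target_metabolite)
    pk <- find_peak(res, sc$target_metabolite)
    auc <- sum(diff(res$times) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
    rows[[sc$name]] <- data.frame(
      scenario = sc$name, target = sc$target_metabolite, ok = TRUE,
      final = final_value(res, sc$target_metabolite),
      plateau = pl$reached, plateau_value = pl$value,
      t_peak = pk$t_peak, v_peak = pk$v_peak, auc = auc,
      fold_vs_baseline = NA_real_, error = "", stringsAsFactors = FALSE)
    trajs[[sc$name]] <- res
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  base_final <- report$final[report$scenario == "baseline"]
  if (length(base_final) == 1L && is.finite(base_final) && base_final > 0)
    report$fold_vs_baseline <- report$final / base_final
  key <- switch(rank_by, final = report$final, peak = report$v_peak,
                auc = report$auc)
  report <- report[order(-key, na.last = TRUE), , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  structure(list(report = report, trajectories = trajs, rank_by = rank_by),
            class = "thiamsim_scan")
}

#' @export
print.thiamsim_scan <- function(x, ...) {
  cat("<thiamsim overexpression scan> ranked by", x$rank_by, "\n")
  print(x$report[, c("rank", "scenario", "final", "fold_vs_baseline",
                     "v_peak", "t_peak", "plateau")], row.names = FALSE)
  invisible(x)
}
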