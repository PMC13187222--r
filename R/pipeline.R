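# Pipeline orchestration: run the five-stage validation end-to-end from a
# configuration, with machine-readable reports, plus named synthetic
# fixtures with ground-truth records.

FIXTURES <- c("null_model", "two_factor_invariant", "metric_violation",
              "sample1_like", "sample3_like")

#' Generate a named synthetic fixture with its ground truth
#'
#' Available fixtures:
#' \describe{
#'   \item{null_model}{65 items, two factors, no group effect (all-zero d
#'     profile), 196 + 196 participants.}
#'   \item{two_factor_invariant}{18 items (12 + 6 block structure, loadings
#'     0.7, factor correlation 0.58), fully invariant measurement; the group
#'     effect is a pure latent factor-mean shift (1.5 on each factor),
#'     500 + 500 participants.}
#'   \item{metric_violation}{as two_factor_invariant, but four case-group
#'     loadings (two per factor) lowered by 0.3.}
#'   \item{sample1_like}{65 items, two correlated factors, 196 + 196
#'     participants, per-item d profile spanning 0.80 to 2.44, reverse-keyed
#'     items IP6, IP13, IP21, IP55.}
#'   \item{sample3_like}{as sample1_like with 30 + 30 participants.}
#' }
#'
#' @param name fixture id.
#' @param seed RNG seed.
#' @param out_dir optional directory; if given, writes `<name>.csv`
#'   (responses) and `<name>_truth.json` (ground truth).
#' @return List with `matrix` (a [response_matrix()]), `config` (the
#'   [sim_config()]) and `ground_truth` (true loadings, factor correlation,
#'   d profile, reverse items, noninvariance).
#' @export
make_fixture <- function(name, seed = 1L, out_dir = NULL) {
  if (!name %in% FIXTURES)
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURES, collapse = ", "))
  cfg <- switch(
    name,
    null_model = sim_config(n_per_group = c(196L, 196L), seed = seed),
    two_factor_invariant = two_factor_config(seed, violate = FALSE),
    metric_violation = two_factor_config(seed, violate = TRUE),
    sample1_like = sample_like_config(c(196L, 196L), seed),
    sample3_like = sample_like_config(c(30L, 30L), seed))
  m <- generate_responses(cfg)
  truth <- list(
    fixture = name,
    loadings = cfg$loadings,
    factor_correlation = cfg$phi,
    d_profile = vapply(seq_len(cfg$n_items), function(j)
      implied_observed_d(cfg$thresholds[j, ], cfg$group_shift[j]), numeric(1)),
    reverse_items = cfg$reverse_items,
    noninvariance = !is.null(cfg$noninvariance))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_responses(m, file.path(out_dir, paste0(name, ".csv")))
    write_sim_config(cfg, file.path(out_dir, paste0(name, "_config.json")))
    jsonlite::write_json(truth, file.path(out_dir, paste0(name, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(matrix = m, config = cfg, ground_truth = truth)
}

# 18-item two-factor configuration used by the invariance fixtures: the
# case-group effect is a latent factor-mean shift, expressed as the
# per-item offsets loadings %*% alpha (scalar-invariant generation).
two_factor_config <- function(seed, violate = FALSE) {
  p <- 18L
  loadings <- matrix(0, p, 2)
  loadings[1:12, 1] <- 0.7
  loadings[13:18, 2] <- 0.7
  alpha <- c(1.5, 1.5)
  noninv <- NULL
  if (violate) {
    pert <- matrix(0, p, 2)
    pert[1:2, 1] <- -0.3
    pert[13:14, 2] <- -0.3
    noninv <- list(loadings = pert)
  }
  sim_config(n_per_group = c(500L, 500L), n_items = p, n_factors = 2L,
             loadings = loadings, factor_correlation = 0.58,
             group_shift = as.vector(loadings %*% alpha),
             reverse_items = character(), noninvariance = noninv,
             seed = seed)
}

# 65-item two-factor configuration with a calibrated discrimination profile
# spanning d = 0.80 .. 2.44 (the emulated study range), reverse-keyed items
# 6, 13, 21, 55.
sample_like_config <- function(n_per_group, seed) {
  p <- 65L
  loadings <- matrix(0, p, 2)
  loadings[1:40, 1] <- 0.7
  loadings[41:65, 2] <- 0.7
  cfg <- sim_config(n_per_group = n_per_group, n_items = p, n_factors = 2L,
                    loadings = loadings, factor_correlation = 0.58,
                    seed = seed)
  targets <- seq(0.80, 2.44, length.out = p)
  # deterministic interleave so both factor blocks span the whole d range
  targets <- targets[c(seq(1, p, by = 2), seq(2, p, by = 2))]
  induce_d_profile(targets, cfg)
}

#' Run the multi-stage validation pipeline
#'
#' Executes the requested stages in dependency order on a response matrix:
#' \describe{
#'   \item{item_selection}{item discrimination, thresholded correlation
#'     network, walktrap communities, centralities, multi-strategy
#'     selection;}
#'   \item{efa}{factorability, parallel analysis, PAF + oblimin on the
#'     selected (or configured) items;}
#'   \item{invariance}{configural/metric/scalar sequence for the configured
#'     CFA spec;}
#'   \item{validity}{total-score group comparison (Welch t, Cohen's d),
#'     reliability, ROC with Youden operating point;}
#'   \item{cfa}{ordinal CFA of the configured spec in the case group;}
#'   \item{extended}{re-runs validity and cfa on a second response matrix
#'     (`extended_input`), emulating replication in an independent sample.}
#' }
#' A stage failure is recorded in the bundle and dependent stages are
#' skipped with a reason.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `input` (path to a response CSV, or a `response_matrix`),
#'   `stages` (character subset of the six stage names),
#'   `network` (list: `threshold`, `steps`, `min_community_size`,
#'   `k_isolated`, `k_hubs`, `k_top`), `efa` (list: `n_factors`,
#'   `n_resamples`, `quantile`), `cfa_spec` (a [cfa_spec()] or path to its
#'   JSON), `items` (explicit item list, overrides selection),
#'   `reverse_items`, `roc_direction`, `seed`, `output_dir`,
#'   `extended_input`.
#' @return An object of class `report_bundle`: per-stage results, `warnings`
#'   and run `metadata`. If `output_dir` is set, stage JSONs/CSVs are
#'   written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_pipeline_config(config)
  m <- cfg$input
  bundle <- list()
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)
  seed <- cfg$seed
  out <- cfg$output_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, deps, fn) {
    if (!name %in% cfg$stages) return()
    for (d in deps) {
      ok <- !is.null(bundle[[d]]) && is.null(bundle[[d]][["error"]]) &&
        !isTRUE(bundle[[d]]$skipped)
      if (!ok) {
        bundle[[name]] <<- list(skipped = TRUE,
                                reason = paste("dependency", d, "unavailable"))
        return()
      }
    }
    bundle[[name]] <<- tryCatch(
      withCallingHandlers(fn(), warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) list(error = conditionMessage(e)))
  }

  selected_items <- cfg$items   # explicit list wins over selection

  run_stage("item_selection", character(), function() {
    d <- item_discrimination(m, reverse = cfg$reverse_items)
    corr <- item_correlations(m, reverse = cfg$reverse_items)
    net <- build_network(corr, threshold = cfg$network$threshold)
    part <- walktrap_communities(net, steps = cfg$network$steps)
    cent <- centralities(net)
    sel <- select_items(d, net, part, cent,
                        min_community_size = cfg$network$min_community_size,
                        k_isolated = cfg$network$k_isolated,
                        k_hubs = cfg$network$k_hubs,
                        k_top = cfg$network$k_top)
    if (is.null(selected_items)) selected_items <<- sel$selected
    if (!is.null(out)) {
      write_network(net, file.path(out, "network_edges.csv"))
      jsonlite::write_json(
        list(selected = sel$selected, provenance = sel$provenance,
             communities_covered = sel$communities_covered),
        file.path(out, "selection.json"), auto_unbox = TRUE, pretty = TRUE)
    }
    list(d_values = d, n_network_items = length(net$nodes),
         n_communities = part$n_communities,
         community_sizes = part$sizes,
         selected = sel$selected, provenance = sel$provenance,
         communities_covered = sel$communities_covered)
  })

  items_for <- function() {
    if (is.null(selected_items))
      stop("no item list: run item_selection or set config$items")
    selected_items
  }

  run_stage("efa", if (is.null(cfg$items)) "item_selection" else character(),
            function() {
    sub <- recode_reversed(subset_items(m, items_for()),
                           intersect(cfg$reverse_items, items_for()))
    fit <- efa_paf(sub, n_factors = cfg$efa$n_factors,
                   n_resamples = cfg$efa$n_resamples,
                   quantile = cfg$efa$quantile, seed = seed + 101L)
    if (!is.null(out))
      utils::write.csv(fit$loadings, file.path(out, "efa_loadings.csv"))
    fit
  })

  run_stage("invariance", character(), function() {
    invariance_sequence(recode_reversed(m, cfg$reverse_items), cfg$cfa_spec)
  })

  run_stage("validity", if (is.null(cfg$items)) "item_selection" else character(),
            function() {
    validity_stage(m, items_for(), cfg$reverse_items, cfg$roc_direction,
                   out = out)
  })

  run_stage("cfa", character(), function() {
    mm <- recode_reversed(m, cfg$reverse_items)
    case_only <- response_subset_group(mm, "case")
    fit_cfa(case_only, cfg$cfa_spec)
  })

  run_stage("extended", "cfa", function() {
    m2 <- cfg$extended_input
    list(validity = validity_stage(m2, items_for(), cfg$reverse_items,
                                   cfg$roc_direction, out = NULL),
         cfa = fit_cfa(response_subset_group(
           recode_reversed(m2, cfg$reverse_items), "case"), cfg$cfa_spec))
  })

  metadata <- list(schema_version = "1.0",
                   package_version = as.character(utils::packageVersion("scalenet")),
                   seed = seed, timestamp = format(Sys.time(), tz = "UTC"))
  res <- structure(list(stages = bundle, warnings = warnings_log,
                        metadata = metadata),
                   class = "report_bundle")
  if (!is.null(out)) write_report(res, file.path(out, "report.json"))
  res
}

validity_stage <- function(m, items, reverse, roc_direction, out = NULL) {
  totals <- score_total(m, items, reverse = reverse)
  a <- summarise_group(totals[m$group == "case"])
  b <- summarise_group(totals[m$group == "comparison"])
  wt <- welch_t(a, b)
  roc <- roc_curve(totals, m$group, direction = roc_direction)
  if (!is.null(out)) write_roc(roc, file.path(out, "roc_curve.csv"))
  list(case = a, comparison = b, welch = wt, cohens_d = cohens_d(a, b),
       alpha = cronbach_alpha(recode_reversed(m, reverse), items),
       auc = roc$auc, youden = youden_optimal(roc), roc = roc)
}

# Subset a response matrix to one group; keeps one participant of the other
# group is NOT done - single-group matrices are allowed internally.
response_subset_group <- function(m, keep) {
  idx <- m$group == keep
  structure(list(values = m$values[idx, , drop = FALSE],
                 group = m$group[idx],
                 item_ids = m$item_ids,
                 participant_ids = m$participant_ids[idx],
                 n_categories = m$n_categories),
            class = "response_matrix")
}

validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  stages_all <- c("item_selection", "efa", "invariance", "validity", "cfa",
                  "extended")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  input <- config$input
  if (is.character(input)) {
    if (!file.exists(input)) stop("input file does not exist: ", input)
    input <- read_responses(input)
  }
  if (inherits(input, "sim_config")) input <- generate_responses(input)
  if (!inherits(input, "response_matrix"))
    stop("config$input must be a CSV path, sim_config, or response_matrix")
  cfa_spec_obj <- config$cfa_spec
  if (is.character(cfa_spec_obj)) {
    if (!file.exists(cfa_spec_obj))
      stop("cfa spec file does not exist: ", cfa_spec_obj)
    cfa_spec_obj <- read_cfa_spec(cfa_spec_obj)
  }
  if (any(c("cfa", "invariance") %in% stages) && is.null(cfa_spec_obj))
    stop("stages 'cfa'/'invariance' require config$cfa_spec")
  if ("extended" %in% stages) {
    if (is.null(config$extended_input))
      stop("stage 'extended' requires config$extended_input")
    if (is.character(config$extended_input))
      config$extended_input <- read_responses(config$extended_input)
    if (inherits(config$extended_input, "sim_config"))
      config$extended_input <- generate_responses(config$extended_input)
  }
  if ("validity" %in% stages && is.null(config$items) &&
      !"item_selection" %in% stages)
    stop("stage 'validity' requires item_selection or an explicit config$items")
  network_defaults <- list(threshold = 0.70, steps = 4L,
                           min_community_size = 2L, k_isolated = 5L,
                           k_hubs = 8L, k_top = 12L)
  efa_defaults <- list(n_factors = NULL, n_resamples = 1000L, quantile = 0.95)
  network <- utils::modifyList(network_defaults, config$network %||% list())
  efa <- utils::modifyList(efa_defaults, config$efa %||% list(),
                           keep.null = TRUE)
  list(input = input, stages = stages, network = network, efa = efa,
       cfa_spec = cfa_spec_obj, items = config$items,
       reverse_items = config$reverse_items %||% character(),
       roc_direction = config$roc_direction %||% "auto",
       seed = as.integer(config$seed %||% 1L),
       output_dir = config$output_dir,
       extended_input = config$extended_input)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Pipeline report (schema", x$metadata$schema_version, "- seed",
      x$metadata$seed, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    status <- if (!is.null(s[["error"]])) paste("ERROR:", s[["error"]])
    else if (isTRUE(s[["skipped"]])) paste("skipped:", s[["reason"]])
    else "ok"
    cat(sprintf("  %-15s %s\n", nm, status))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

# Serialise a report bundle to JSON (classed objects reduced to plain
# lists; matrices to row-major lists with dimnames kept).
write_report <- function(bundle, path) {
  strip <- function(x) {
    if (inherits(x, "response_matrix")) return(NULL)
    if (is.environment(x) || inherits(x, "lm") || inherits(x, "igraph"))
      return(NULL)
    if (is.list(x)) {
      x <- unclass(x)
      out <- lapply(x, strip)
      return(out[!vapply(out, is.null, logical(1))])
    }
    x
  }
  jsonlite::write_json(strip(unclass(bundle)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
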