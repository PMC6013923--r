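#' Default reaction panel for cross-diet reports
#'
#' The carbohydrate-entry and TCA reactions plus the per-species
#' beta-oxidation reactions tracked in the dietary comparisons.
#'
#' @return Character vector of reaction ids.
#' @export
default_report_reactions <- function() {
  c("PDHm", "CSm", "ICDHxm", "AKGDm",
    "FAOXC140", "FAOXC160", "FAOXC180", "FAOXC181", "FAOXC182",
    "FAOXC205", "FAOXC226")
}

#' Default study configuration
#'
#' Reduced scale (500 points, 100 steps between points) keeps a full
#' seven-diet run in the minutes range; `full_scale = TRUE` switches to the
#' reference study protocol of 2000 points with 500 steps.
#'
#' @param diets Diet names to run (default: all seven builtin diets).
#' @param seed Base seed; per-diet chains use `seed + diet index - 1`.
#' @param full_scale Use the full-length sampling protocol (2000 points, 500 steps).
#' @return Nested configuration list accepted by [run_study()].
#' @export
study_config <- function(diets = names(builtin_diets()), seed = 1,
                         full_scale = FALSE) {
  list(
    model = list(source = "fixture", include_marine_fa = TRUE),
    diets = diets,
    physiology = NULL,            # NULL = default_physiology() per diet
    reactions = default_report_reactions(),
    sampler = list(n_points = if (full_scale) 2000L else 500L,
                   steps_per_point = if (full_scale) 500L else 100L,
                   seed = seed,
                   optimality_fraction = 0.99),
    alpha = 0.05
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full diet study pipeline
#'
#' Orchestrates build (or load) -> constrain -> integrity check -> ACHR
#' sampling per diet -> per-reaction summaries -> cross-diet ANOVA /
#' Tukey-Kramer comparisons -> report, writing TSV tables, JSON sidecars
#' and a run manifest sufficient to reproduce the run into `output_dir`.
#' Stage failures abort with stage-named diagnostics; outputs written by
#' completed stages are preserved.
#'
#' @param config Configuration list as produced by [study_config()], or the
#'   path of a YAML file with the same structure.
#' @param output_dir Output directory (created if needed); `NULL` runs
#'   fully in memory.
#' @return Invisibly, a list of class `"study_result"` with elements
#'   `model`, `samples` (named list of `"flux_samples"`), `summaries`,
#'   `comparisons`, `manifest`, `output_dir`.
#' @export
run_study <- function(config = study_config(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$diets) || !length(config$diets)) {
    stop("config must name at least one diet")
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  emit <- function(name, writer) {
    if (!is.null(output_dir)) writer(file.path(output_dir, name))
  }

  model <- run_stage("build", {
    src <- config$model$source %||% "fixture"
    if (identical(src, "fixture")) {
      build_fixture_model(
        include_marine_fa = config$model$include_marine_fa %||% TRUE)
    } else {
      load_model(src)
    }
  })
  emit("model.json", function(p) write_model(model, p, "native-json"))
  emit("model_reactions.tsv", function(p) write_reaction_table(model, p))

  integrity <- run_stage("check", check_model_integrity(model))
  if (!integrity$atp_producible) {
    stop("pipeline stage 'check' failed: model cannot produce ATP")
  }

  diets <- run_stage("constrain", {
    all_diets <- builtin_diets()
    unknown <- setdiff(config$diets, names(all_diets))
    if (length(unknown)) {
      stop("unknown diet(s): ", paste(unknown, collapse = ", "))
    }
    all_diets[config$diets]
  })

  sc <- config$sampler %||% list()
  base_seed <- sc$seed %||% 1L
  samples <- list()
  for (k in seq_along(diets)) {
    dname <- names(diets)[k]
    samples[[dname]] <- run_stage(paste0("sample:", dname), {
      phys <- if (is.null(config$physiology)) default_physiology(dname)
              else do.call(physiology_params, config$physiology)
      ub <- compute_uptake_bounds(diets[[dname]], phys)
      constrained <- apply_diet(model, ub)
      cfg <- sampler_config(
        n_points = sc$n_points %||% 500L,
        steps_per_point = sc$steps_per_point %||% 100L,
        n_warmup = sc$n_warmup,
        seed = base_seed + k - 1L,
        optimality_fraction = sc$optimality_fraction %||% 0.99)
      fs <- achr_sample(constrained, cfg)
      emit(paste0("samples_", dname, ".tsv"), function(p) {
        utils::write.table(signif(fs$samples, 10), p, sep = "\t",
                           quote = FALSE, col.names = FALSE)
      })
      emit(paste0("samples_", dname, ".json"), function(p) {
        jsonlite::write_json(
          list(diet = dname, config = unclass(fs$config), dim = fs$dim,
               n_reactions = nrow(fs$samples), validity = fs$validity),
          p, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
      })
      fs
    })
  }

  reactions <- intersect(config$reactions %||% default_report_reactions(),
                         reaction_ids(model))
  summaries <- run_stage("summarize", {
    do.call(rbind, lapply(names(samples), function(dname) {
      cbind(diet = dname, summarize_fluxes(samples[[dname]], reactions))
    }))
  })

  comparisons <- NULL
  if (length(samples) >= 2) {
    comparisons <- run_stage("compare", {
      out <- lapply(reactions, function(r)
        compare_groups(samples, r, alpha = config$alpha %||% 0.05))
      stats::setNames(out, reactions)
    })
  } else {
    message("single diet configured; comparison stage skipped")
  }

  report <- run_stage("report", {
    rep <- summaries
    rep$letters <- ""
    if (!is.null(comparisons)) {
      for (r in names(comparisons)) {
        cmp <- comparisons[[r]]
        idx <- rep$reaction == r
        rep$letters[idx] <- cmp$letters[match(rep$diet[idx], cmp$group_labels)]
      }
    }
    emit("flux_report.tsv", function(p) {
      utils::write.table(rep, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    if (!is.null(comparisons)) {
      emit("comparisons.json", function(p) {
        jsonlite::write_json(
          lapply(comparisons, function(cmp)
            list(reaction = cmp$reaction_id, anova_F = cmp$anova_F,
                 anova_p = cmp$anova_p,
                 tukey_pairwise = as.data.frame(cmp$tukey_pairwise),
                 letters = as.list(cmp$letters))),
          p, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
      })
    }
    rep
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mitoflux")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    model_source = config$model$source %||% "fixture",
    include_marine_fa = config$model$include_marine_fa %||% TRUE,
    diets = names(diets),
    physiology = if (is.null(config$physiology)) "default_physiology per diet"
                 else config$physiology,
    sampler = list(n_points = sc$n_points %||% 500L,
                   steps_per_point = sc$steps_per_point %||% 100L,
                   base_seed = base_seed,
                   per_diet_seeds = base_seed + seq_along(diets) - 1L,
                   optimality_fraction = sc$optimality_fraction %||% 0.99),
    alpha = config$alpha %||% 0.05,
    reactions = reactions,
    integrity = list(atp_producible = integrity$atp_producible,
                     max_atp_open_exchanges = integrity$max_atp,
                     dead_ends = integrity$dead_ends),
    outputs = if (is.null(output_dir)) list() else
      as.list(list.files(output_dir))
  )
  emit("manifest.json", function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })

  invisible(structure(
    list(model = model, integrity = integrity, samples = samples,
         summaries = summaries, comparisons = comparisons,
         report = report, manifest = manifest, output_dir = output_dir),
    class = "study_result"))
}

#' @export
print.study_result <- function(x, ...) {
  cat("Diet study run: ", length(x$samples), " diet(s), ",
      length(unique(x$summaries$reaction)), " reported reaction(s)\n", sep = "")
  if (!is.null(x$output_dir)) cat("  outputs in ", x$output_dir, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
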