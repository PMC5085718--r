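#' Run the full modeling pipeline
#'
#' Chains the stages extract -> screen -> train -> evaluate for each
#' requested reaction type and writes all artifacts (MMRS descriptor
#' table, screening scores, search grid, winning bundle, quality report,
#' run manifest) under `out_dir`.  Inputs are either a structure file with
#' annotations/registry or a synthetic library generated on the fly.
#'
#' @param config named list.  Recognized entries:
#' \describe{
#'   \item{out_dir}{artifact directory (required).}
#'   \item{seed}{global seed; all stage seeds derive from it (default 1).}
#'   \item{reactions}{reaction types to model (default all four).}
#'   \item{simulate}{list(n_molecules, ...) to generate a toy library, or}
#'   \item{input}{list(structures, format, annotations, registry).}
#'   \item{vote_threshold}{screening vote cut (default 5).}
#'   \item{folds}{CV folds everywhere (default 10).}
#'   \item{fs_methods, classifiers}{search grid axes (defaults: all).}
#'   \item{exclude_amide_n}{pattern III switch (default FALSE).}
#' }
#' @return named list per reaction: modeling set, search, selection,
#'   bundle, report; plus `mmrs` and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  reactions <- config$reactions %||% REACTION_TYPES
  folds <- config$folds %||% 10L
  vote_threshold <- config$vote_threshold %||% 5L
  fs_methods <- config$fs_methods %||% FS_METHODS
  classifiers <- config$classifiers %||% classifier_roster()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # ---- inputs ----
  inputs <- stage("input", {
    if (!is.null(config$simulate)) {
      lib <- make_toy_library(config$simulate$n_molecules %||% 200L,
                              seed = seed)
      dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE)
      write_toy_library(lib, file.path(out_dir, "inputs"))
      mols <- parse_smiles_set(lib$smiles$smiles, lib$smiles$mol_id)
      list(mols = mols, annotations = lib$annotations,
           registry = lib$registry)
    } else {
      inp <- config$input
      mols <- read_structures(inp$structures, inp$format %||% "sdf")
      ann <- read_som_annotations(inp$annotations)
      reg <- if (!is.null(inp$registry)) read_enzyme_registry(inp$registry)
             else NULL
      list(mols = mols, annotations = ann, registry = reg)
    }
  })
  flt <- stage("filter", filter_elements(inputs$mols))
  if (nrow(flt$removed))
    message("removed ", nrow(flt$removed), " molecule(s) by element filter")
  # ---- extract ----
  mmrs <- stage("extract",
    extract_mmrs(flt$kept, inputs$annotations, inputs$registry,
                 exclude_amide_n = isTRUE(config$exclude_amide_n)))
  write_mmrs_table(mmrs$records, mmrs$vectors,
                   file.path(out_dir, "mmrs.csv"))
  datasets <- build_reaction_datasets(mmrs)
  results <- list()
  for (rt in reactions) {
    ds <- datasets[[rt]]
    scr <- stage(paste0("screen/", rt),
      screen_negatives(ds, seed = seed, vote_threshold = vote_threshold,
                       folds = folds, classifiers = classifiers))
    utils::write.csv(scr$scores,
                     file.path(out_dir, paste0("screening_", rt, ".csv")),
                     row.names = FALSE)
    ms <- stage(paste0("split/", rt),
                build_modeling_set(ds, scr$negatives, seed = seed))
    search <- stage(paste0("train/", rt), {
      ytr <- factor(ifelse(ms$train$records$label == "positive",
                           "pos", "neg"), levels = c("neg", "pos"))
      run_model_search(ms$train$vectors, ytr, fs_methods = fs_methods,
                       classifiers = classifiers, folds = folds,
                       seed = seed)
    })
    utils::write.csv(search$grid,
                     file.path(out_dir, paste0("grid_", rt, ".csv")),
                     row.names = FALSE)
    selection <- stage(paste0("select/", rt), select_optimal(search))
    bundle <- stage(paste0("fit/", rt), {
      ytr <- factor(ifelse(ms$train$records$label == "positive",
                           "pos", "neg"), levels = c("neg", "pos"))
      fit_final(ms$train$vectors, ytr, selection, reaction_type = rt,
                seed = seed)
    })
    save_model_bundle(bundle, file.path(out_dir, paste0("model_", rt)))
    report <- stage(paste0("evaluate/", rt),
                    evaluate_bundle(bundle, ms, folds = folds, seed = seed))
    utils::write.csv(cbind(dataset = rownames(report), round(report, 3)),
                     file.path(out_dir, paste0("report_", rt, ".csv")),
                     row.names = FALSE)
    results[[rt]] <- list(modeling_set = ms, screening = scr,
                          search = search, selection = selection,
                          bundle = bundle, report = report)
  }
  manifest <- list(
    seed = seed, reactions = reactions, folds = folds,
    vote_threshold = vote_threshold, fs_methods = fs_methods,
    classifiers = classifiers,
    n_molecules = length(flt$kept),
    n_mmrs = nrow(mmrs$records),
    package_version = as.character(utils::packageVersion("mmrsom")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(mmrs = mmrs, datasets = datasets,
                            out_dir = out_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
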