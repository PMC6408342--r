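#' Load a workflow configuration
#'
#' Configurations are plain lists, read from YAML or JSON. See
#' [run_workflow()] for the recognized fields.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

build_correlation_from_config <- function(cc, labels) {
  builder <- cc$builder %||% abort("correlation config needs a 'builder'")
  eta <- cc$eta %||% 0.01
  switch(
    builder,
    constant = constant_correlation(labels),
    group = {
      df <- read.table(cc$groups, header = TRUE, sep = detect_sep(cc$groups),
                       colClasses = "character")
      g <- setNames(df[[2]], df[[1]])[labels]
      group_correlation(g, eta = eta)
    },
    exponential = {
      df <- read.table(cc$traits, header = TRUE, sep = detect_sep(cc$traits),
                       row.names = 1L, check.names = FALSE)
      exponential_correlation(as.matrix(df)[labels, , drop = FALSE], eta = eta)
    },
    phylogenetic = phylogenetic_correlation(cc$tree, tip_labels = labels),
    file = read_correlation(cc$file),
    abort(paste0("unknown correlation builder: ", builder))
  )
}

load_input_from_config <- function(cfg) {
  inp <- cfg$input %||% abort("config needs an 'input' section")
  if (!is.null(inp$synthetic)) {
    sp <- inp$synthetic
    seed <- cfg$seed %||% 1L
    switch(
      sp$kind %||% abort("synthetic input needs a 'kind'"),
      assemblage = {
        w <- synthetic_assemblage(sp$n_sites %||% 20, sp$n_species %||% 30,
                                  gamma = sp$gamma %||% 0.9,
                                  strength = sp$strength %||% 5,
                                  seed = seed)
        list(matrix = w$incidence, world = w)
      },
      foodweb = {
        tw <- simulate_tree_and_traits(sp$n_species %||% 20, seed = seed)
        w <- synthetic_foodweb(tw, beta = sp$beta %||% 2,
                               density = sp$density %||% 0.15, seed = seed + 1)
        list(matrix = w$web, world = w)
      },
      random = {
        list(matrix = random_binary_matrix(sp$n %||% 20, sp$m %||% 20,
                                           fill = sp$fill %||% 0.2,
                                           seed = seed),
             world = NULL)
      },
      abort(paste0("unknown synthetic kind: ", sp$kind))
    )
  } else {
    A <- read_incidence(inp$matrix %||% abort("input needs 'matrix' or 'synthetic'"),
                        format = inp$format %||% "matrix_csv",
                        food_web = isTRUE(inp$food_web))
    list(matrix = A, world = NULL)
  }
}

#' Run the full estimate-randomize-measure-test workflow
#'
#' Executes the whole pipeline from a single configuration: load (or
#' synthesize) the incidence matrix, build the correlation structure,
#' estimate link probabilities where the model calls for them, generate
#' the null ensemble, measure the requested structural metrics on the
#' observed matrix and every replicate, and score them with z-scores
#' (significance at |z| >= 1.96). Results are written as a JSON report
#' plus a TSV table; progress is logged to stderr; everything is
#' reproducible from the embedded config and master seed.
#'
#' Recognized config fields (YAML/JSON): `input` (`matrix` + `format` +
#' `food_web`, or `synthetic` with `kind` = assemblage/foodweb/random and
#' generator parameters), `model` (`kind` = uninformed/informed/
#' misinformed; `correlation` with `builder` = constant/group/
#' exponential/phylogenetic/file and its parameters; `perspective` =
#' rows/cols), `metrics` (any of `"nodf"`, `"motifs"`), `ensemble`
#' (`size`, optional `target_accepted` / `max_trials`), `seed`,
#' `output_dir`.
#'
#' @param config a list, or a path to a YAML/JSON config file.
#' @param output_dir overrides `config$output_dir`; `NULL` disables file
#'   output.
#' @return (invisibly) a list with `results` (tibble of metric rows),
#'   `ensemble`, `config`.
#' @export
run_workflow <- function(config, output_dir = config$output_dir) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed %||% 1L
  logmsg <- function(...) message("[corrnull] ", sprintf(...))
  logmsg("R %s, corrnull %s, master seed %d", getRversion(),
         as.character(utils::packageVersion("corrnull")), as.integer(seed))

  stage <- "input"
  out <- tryCatch({
    inp <- load_input_from_config(config)
    A <- inp$matrix
    is_web <- inherits(A, "food_web")
    logmsg("input: %d x %d %s, %d links", nrow(A), ncol(A),
           if (is_web) "food web" else "incidence matrix", sum(A))

    stage <- "correlation"
    mk <- (config$model %||% list())$kind %||% "uninformed"
    perspective <- (config$model %||% list())$perspective %||% "rows"
    V <- NULL
    if (mk != "uninformed") {
      axis_labels <- if (perspective == "rows") colnames(A) else rownames(A)
      V <- build_correlation_from_config(config$model$correlation, axis_labels)
      logmsg("correlation: %s builder over %d elements",
             attr(V, "provenance")$builder, nrow(V))
    }

    stage <- "randomize"
    ens_cfg <- config$ensemble %||% list()
    budget <- if (!is.null(ens_cfg$target_accepted)) {
      swap_budget(ens_cfg$target_accepted,
                  ens_cfg$max_trials %||% (50 * ens_cfg$target_accepted))
    } else NULL
    size <- ens_cfg$size %||% 200
    ens <- build_ensemble(A, model = mk, V = V, perspective = perspective,
                          size = size, budget = budget, seed = seed)
    logmsg("ensemble: %d %s replicates, mean overlap %.3f", size, mk,
           mean(tidy(ens)$overlap))

    stage <- "measure"
    metrics <- config$metrics %||% if (is_web) "motifs" else "nodf"
    rows <- list()
    if ("nodf" %in% metrics) {
      r <- nodf_zscore(A, ens)
      rows$nodf <- dplyr::bind_cols(tibble(metric = "nodf", class = NA_character_,
                                           motif = NA_character_), r)
    }
    if ("motifs" %in% metrics) {
      r <- motif_zscore_profile(as_food_web(A), ens)
      rows$motifs <- dplyr::bind_cols(tibble(metric = "motif_count"),
                                      as_tibble(r))
    }
    results <- dplyr::bind_rows(rows)
    list(results = results, ensemble = ens)
  }, error = function(e) {
    abort(paste0("workflow failed at stage '", stage, "': ", conditionMessage(e)))
  })

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      config = config,
      seed = seed,
      corrnull_version = as.character(utils::packageVersion("corrnull")),
      significance_threshold = z_significance_threshold(),
      ensemble = list(model = out$ensemble$model,
                      size = length(out$ensemble$matrices),
                      budget = unclass(out$ensemble$budget),
                      mean_overlap = mean(tidy(out$ensemble)$overlap)),
      results = out$results
    )
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    write.table(out$results, file.path(output_dir, "report.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    logmsg("report written to %s", output_dir)
  }
  invisible(c(out, list(config = config)))
}
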