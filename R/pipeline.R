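#' Default end-to-end run configuration
#'
#' @param out_dir output directory.
#' @param seed master seed (drives cohort, injection, walks and training).
#' @param n_patients cohort size.
#' @return config list accepted by [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("rolhs_run_"), seed = 1L,
                           n_patients = 100L) {
  list(seed = as.integer(seed),
       n_patients = as.integer(n_patients),
       group_weights = rep(1, 5),
       error_rates = list(type = 0.05, cross_field = 0.05,
                          mandatory = 0.05, range = 0.05, format = 0.05),
       ontology_path = NULL,     # NULL = bundled synthetic fixture
       rules_path = NULL,        # NULL = default_rules()
       mapping_spec_path = NULL, # NULL = default_mapping_spec()
       search = list(terms = c("fatigue"), synonyms = TRUE,
                     child_levels = 1L, parents = FALSE),
       walks = list(n = 10L, length = 20L),
       embedding = list(kind = "word2vec", dim = 100L, window = 5L,
                        epochs = 100L, negative = 5L),
       similar_k = 10L,
       out_dir = out_dir)
}

read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_config()
  utils::modifyList(base, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' generate -> inject errors (optional) -> validate -> clean -> map to
#' RDF -> serialize Turtle -> ontology search -> walk corpus ->
#' embedding -> similarity ranking -> cluster evaluation -> manifest.
#' Outputs land in `config$out_dir`; identical config and seed give
#' byte-identical Turtle and corpus outputs. Partial outputs are retained
#' when a stage fails (the error names the stage).
#'
#' @param config list as from [default_config()], or path to a JSON file.
#' @return the output directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  seed <- as.integer(config$seed)

  ont <- stage("ontology", {
    path <- config$ontology_path
    if (is.null(path)) {
      path <- file.path(od, "ontology.json")
      write_fixture_ontology(path)
    }
    load_ontology(path)
  })

  tables <- stage("generate", {
    t <- generate_cohort(config$n_patients, config$group_weights, seed)
    write_cohort_csv(t, file.path(od, "cohort"))
    write_cohort_json(t, file.path(od, "cohort.json"))
    t
  })

  ledger <- NULL
  rates <- unlist(config$error_rates %||% list())
  if (length(rates) && any(rates > 0)) {
    inj <- stage("inject_errors",
                 inject_errors(tables, rates, seed = seed + 1L))
    tables <- inj$tables
    ledger <- inj$ledger
    utils::write.csv(ledger, file.path(od, "error_ledger.csv"),
                     row.names = FALSE)
  }

  rules <- stage("rules", if (is.null(config$rules_path)) default_rules()
                 else read_rules(config$rules_path))
  report <- stage("validate", validate(tables, rules))
  jsonlite::write_json(
    list(violations = report$violations, summary = report$summary),
    file.path(od, "validation_report.json"), dataframe = "rows",
    auto_unbox = TRUE, pretty = TRUE)
  cleaned <- stage("clean", clean(tables, report))
  write_cohort_csv(cleaned, file.path(od, "cohort_clean"))

  spec <- stage("mapping_spec",
                if (is.null(config$mapping_spec_path)) default_mapping_spec()
                else read_mapping_spec(config$mapping_spec_path))
  store <- stage("map", compile_mapping(spec, cleaned, ont))
  stats <- attr(store, "stats")
  stage("turtle", serialize_turtle(store, file.path(od, "graph.ttl")))

  sr <- NULL
  if (length(config$search$terms)) {
    sr <- stage("search", {
      opts <- search_options(
        include_synonyms = isTRUE(config$search$synonyms),
        child_levels = config$search$child_levels %||% 1L,
        include_parents = isTRUE(config$search$parents))
      r <- search(store, ont, config$search$terms, opts)
      write_search_result(r, file.path(od, "search.json"))
      r
    })
  }

  corpus <- stage("walks", {
    cp <- build_walk_corpus(store, walks_per_patient = config$walks$n,
                            max_walk_length = config$walks$length,
                            seed = seed + 2L)
    write_corpus(cp, file.path(od, "corpus.txt"))
    cp
  })

  emb <- config$embedding
  model <- stage("embedding",
                 train_embedding(corpus, emb$kind, dim = emb$dim,
                                 window = emb$window, epochs = emb$epochs,
                                 negative = emb$negative,
                                 seed = seed + 3L,
                                 background = ontology_corpus(ont)))
  vecs <- stage("vectors", {
    v <- patient_vectors(model, corpus)
    write_vectors(v, file.path(od, "patient_vectors.txt"))
    v
  })

  ranking <- stage("similar", {
    q <- rownames(vecs)[1]
    r <- rank_similar(vecs, q, metric = "cosine",
                      k = config$similar_k %||% 10L)
    utils::write.csv(cbind(query = q, r),
                     file.path(od, "similar.csv"), row.names = FALSE)
    r
  })

  eval_report <- stage("evaluate", {
    pid <- sub(".*/patient/", "", rownames(vecs))
    labels <- stats::setNames(
      tables$diagnosis$diagnosis_group[
        match(pid, tables$diagnosis$patient_id)], rownames(vecs))
    rep <- evaluate_clusters(vecs, labels)
    write_cluster_report(rep, file.path(od, "cluster_report.json"),
                         file.path(od, "cluster_report.tsv"))
    rep
  })

  manifest <- list(
    package = "rolhs",
    version = as.character(utils::packageVersion("rolhs")),
    seed = seed,
    n_patients = nrow(tables$demographics),
    table_rows = lapply(tables, nrow),
    n_violations = nrow(report$violations),
    n_injected = if (is.null(ledger)) 0L else nrow(ledger),
    n_triples = n_triples(store),
    mapping_completeness = mapping_completeness(stats$applicable,
                                                stats$mapped),
    corpus_sentences = length(corpus$sentences),
    vocab_size = length(corpus$vocab),
    embedding_kind = model$kind,
    intra_mean_cosine = eval_report$intra_mean_cosine,
    inter_mean_cosine = eval_report$inter_mean_cosine,
    search_patients = if (is.null(sr)) NULL else length(sr$patients))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(od)
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}

opt_int <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.integer(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `run-all`, `generate`, `validate`, `map`, `query`,
#' `search`, `similar`, `evaluate`, `dvh`. See the README for flag
#' summaries; an installed launcher lives at
#' `system.file("cli", "rolhs", package = "rolhs")`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the subcommand's main result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: rolhs <run-all|generate|validate|map|query|search|",
        "similar|evaluate|dvh> [--flags]\n", sep = "")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  out <- opts$out %||% "."
  get_ont <- function() {
    if (!is.null(opts$ontology)) load_ontology(opts$ontology)
    else load_ontology(write_fixture_ontology(tempfile(fileext = ".json")))
  }
  res <- switch(
    cmd,
    "run-all" = {
      cfg <- if (!is.null(opts$config)) read_config(opts$config)
      else default_config(out_dir = out,
                          seed = opt_int(opts, "seed", 1L),
                          n_patients = opt_int(opts, "n", 100L))
      if (!is.null(opts$out)) cfg$out_dir <- out
      run_pipeline(cfg)
    },
    generate = {
      w <- if (is.null(opts$weights)) rep(1, 5)
      else as.numeric(strsplit(opts$weights, ",")[[1]])
      t <- generate_cohort(opt_int(opts, "n", 100L), w,
                           opt_int(opts, "seed", 1L))
      write_cohort_csv(t, out)
      t
    },
    validate = {
      t <- read_cohort_csv(opts$tables)
      rules <- if (is.null(opts$rules)) default_rules()
      else read_rules(opts$rules)
      r <- validate(t, rules)
      print(r)
      r
    },
    map = {
      t <- read_cohort_csv(opts$tables)
      spec <- if (is.null(opts$spec)) default_mapping_spec()
      else read_mapping_spec(opts$spec)
      store <- compile_mapping(spec, t, get_ont())
      serialize_turtle(store, opts$graph %||% file.path(out, "graph.ttl"))
      store
    },
    query = {
      store <- parse_turtle(opts$graph)
      pats <- lapply(strsplit(strsplit(opts$pattern, ";")[[1]], "\\|"),
                     trimws)
      b <- query(store, pats)
      cat(jsonlite::toJSON(b, dataframe = "rows", pretty = TRUE), "\n")
      b
    },
    search = {
      store <- parse_turtle(opts$graph)
      terms <- trimws(strsplit(opts$terms, ",")[[1]])
      r <- search(store, get_ont(), terms,
                  search_options(
                    include_synonyms = isTRUE(opts$synonyms),
                    child_levels = opt_int(opts, "child_levels", 1L),
                    include_parents = isTRUE(opts$parents)))
      if (!is.null(opts$out) && !dir.exists(opts$out))
        write_search_result(r, opts$out) else print(r)
      r
    },
    similar = {
      store <- parse_turtle(opts$graph)
      corpus <- build_walk_corpus(store, seed = opt_int(opts, "seed", 1L))
      model <- train_embedding(corpus, opts$model %||% "word2vec",
                               dim = opt_int(opts, "dim", 100L),
                               epochs = opt_int(opts, "epochs", 100L),
                               seed = opt_int(opts, "seed", 1L))
      vecs <- patient_vectors(model, corpus)
      q <- rownames(vecs)[grepl(opts$patient, rownames(vecs),
                                fixed = TRUE)][1]
      r <- rank_similar(vecs, q, metric = opts$metric %||% "cosine",
                        k = opt_int(opts, "k", 10L))
      print(r)
      r
    },
    evaluate = {
      store <- parse_turtle(opts$graph)
      t <- read_cohort_csv(opts$tables)
      corpus <- build_walk_corpus(store, seed = opt_int(opts, "seed", 1L))
      model <- train_embedding(corpus, opts$model %||% "word2vec",
                               dim = opt_int(opts, "dim", 100L),
                               epochs = opt_int(opts, "epochs", 100L),
                               seed = opt_int(opts, "seed", 1L))
      vecs <- patient_vectors(model, corpus)
      pid <- sub(".*/patient/", "", rownames(vecs))
      labels <- stats::setNames(
        t$diagnosis$diagnosis_group[match(pid, t$diagnosis$patient_id)],
        rownames(vecs))
      r <- evaluate_clusters(vecs, labels)
      print(r)
      r
    },
    dvh = {
      g <- generate_dose_grid(prescription_cgy =
                                opt_int(opts, "prescription", 6000),
                              seed = opt_int(opts, "seed", 1L))
      cv <- compute_dvh(g, opts$structure %||% "PTV",
                        bin_width_cgy = opt_int(opts, "bin", 50))
      if (!is.null(opts$out) && !dir.exists(opts$out)) write_dvh(cv, opts$out)
      print(dvh_metrics(cv, c("mean", "max", "D95")))
      cv
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(res)
}
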