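#' Read and write protein FASTA
#'
#' Thin wrappers over Biostrings keeping the package's plain
#' character-vector sequence representation.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a variant-fitness table
#'
#' Reads a TSV with a `score` column and a variant identification as a
#' mutation-string column (`variant`, e.g. `"A23Y,K31M"`, 1-based, `"WT"`
#' for wild type) and/or a full-sequence column (`sequence`). When both
#' are present they are cross-validated against each other. A `split`
#' column (`train`/`val`/`test`) is carried through if present; mutation
#' counts are (re)computed from the sequences.
#'
#' @param path TSV path.
#' @param wild_type Wild-type sequence; required when only mutation
#'   strings are present, used for validation otherwise.
#' @return Fitness dataset data frame (`variant`, `sequence`, `score`,
#'   `n_mut`, and `split` when present).
#' @export
read_fitness_table <- function(path, wild_type = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"score" %in% names(df)) stop("missing 'score' column")
  has_var <- "variant" %in% names(df)
  has_seq <- "sequence" %in% names(df)
  if (!has_var && !has_seq) {
    stop("need a 'variant' (mutation string) or 'sequence' column")
  }
  if (has_var && is.null(wild_type) && !has_seq) {
    stop("wild_type is required to parse mutation strings")
  }
  if (!has_seq) {
    seqs <- vapply(seq_len(nrow(df)), function(i) {
      v <- tryCatch(parse_mutation_string(df$variant[i], wild_type),
                    error = function(e) {
                      stop("line ", i + 1L, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
      variant_sequence(v)
    }, "")
    df$sequence <- seqs
  }
  if (is.null(wild_type)) {
    # infer from an explicit WT row if available, else use the sequences
    wt_row <- if (has_var) which(toupper(trimws(df$variant)) == "WT") else integer()
    wild_type <- if (length(wt_row)) df$sequence[wt_row[1]] else df$sequence[1]
  }
  if (has_var && has_seq) {
    for (i in seq_len(nrow(df))) {
      v <- tryCatch(parse_mutation_string(df$variant[i], wild_type),
                    error = function(e) {
                      stop("line ", i + 1L, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
      if (variant_sequence(v) != df$sequence[i]) {
        stop("line ", i + 1L, ": mutation string and sequence disagree")
      }
    }
  }
  if (!has_var) {
    df$variant <- mutation_strings_from_seqs(df$sequence, wild_type)
  }
  df$n_mut <- vapply(df$sequence, function(s) hamming_distance(s, wild_type),
                     0L, USE.NAMES = FALSE)
  cols <- c("variant", "sequence", "score", "n_mut",
            intersect("split", names(df)))
  df[, cols, drop = FALSE]
}

#' @rdname read_fitness_table
#' @param data Fitness dataset data frame.
#' @export
write_fitness_table <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# known config schema with defaults (anneal defaults are the field-standard
# schedule: T 1e3 -> 1e-5, Poisson lambda 1 moves, 41 clusters)
config_schema <- function() {
  list(
    wild_type_fasta = NULL, fitness_table = NULL, checkpoint_dir = NULL,
    output_dir = NULL, models = NULL, distances = NULL, budgets = NULL,
    seed = 0L,
    anneal = list(t_start = 1e3, t_end = 1e-5, lambda = 1,
                  n_steps = NULL, n_runs = 500L, clusters = 41L))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML run configuration, rejects unknown keys by name, and
#' fills defaults (annealing temperatures 1e3 to 1e-5, Poisson lambda 1,
#' 41 clusters, 500 runs).
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(schema, raw)
  if (!is.null(raw$anneal)) {
    bad <- setdiff(names(raw$anneal), names(schema$anneal))
    if (length(bad)) {
      stop("unknown config key(s): ", paste0("anneal.", bad, collapse = ", "))
    }
    cfg$anneal <- utils::modifyList(schema$anneal, raw$anneal)
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config` (or compatible list).
#' @export
save_config <- function(config, path) {
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_nulls)
    x[!vapply(x, is.null, TRUE)]
  }
  yaml::write_yaml(drop_nulls(unclass(config)), path)
  invisible(path)
}

#' Write a design-campaign manifest and FASTA
#'
#' Serializes the representative designs of one or more campaigns to a
#' FASTA file plus a TSV manifest (model, mutation distance, cluster,
#' mutation string, predicted fitness, run seed), in deterministic
#' (model, k, cluster) order. Sequence names are `model_k<k>_c<cluster>`.
#'
#' @param campaigns List of lists with elements `model` (tag), `k`, and
#'   `representatives` (from [select_representatives()]).
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite existing files (default `FALSE`; an
#'   existing manifest is otherwise an error).
#' @return The manifest data frame, invisibly.
#' @export
write_design_manifest <- function(campaigns, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.tsv")
  fasta_path <- file.path(dir, "designs.fasta")
  if (!overwrite && (file.exists(manifest_path) || file.exists(fasta_path))) {
    stop("output files already exist in ", dir, " (set overwrite = TRUE)")
  }
  rows <- lapply(campaigns, function(cp) {
    reps <- cp$representatives
    reps <- reps[order(reps$cluster), , drop = FALSE]
    data.frame(model = cp$model, k = cp$k, cluster = reps$cluster,
               name = paste0(cp$model, "_k", cp$k, "_c", reps$cluster),
               variant = reps$variant, sequence = reps$sequence,
               predicted_fitness = reps$fitness, run_seed = reps$run_seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) {
    manifest <- data.frame(model = character(), k = integer(),
                           cluster = integer(), name = character(),
                           variant = character(), sequence = character(),
                           predicted_fitness = numeric(),
                           run_seed = numeric(), stringsAsFactors = FALSE)
  } else {
    manifest <- manifest[order(manifest$model, manifest$k, manifest$cluster), ,
                         drop = FALSE]
  }
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(manifest)) {
    write_fasta(setNames(manifest$sequence, manifest$name), fasta_path)
  } else {
    writeLines(character(), fasta_path)
  }
  invisible(manifest)
}

#' Save and load predictor checkpoints
#'
#' Self-describing JSON checkpoints holding the spec, fitted parameters
#' and training history; loading rebuilds a fully functional predictor.
#'
#' @param model A `fitness_model`.
#' @param path Checkpoint path (`.json`).
#' @return `load_predictor` returns the restored model.
#' @export
save_predictor <- function(model, path) {
  stopifnot(inherits(model, "fitness_model"))
  spec <- model$spec
  payload <- list(
    spec = list(architecture = spec$architecture, L = spec$L,
                hidden = spec$hidden, kernel_size = spec$kernel_size,
                filters = spec$filters, channels = spec$channels,
                adjacency = spec$adjacency, seed = spec$seed,
                learning_rate = spec$learning_rate, epochs = spec$epochs,
                batch_size = spec$batch_size, patience = spec$patience),
    params = model$params,
    history = model$history,
    trained = model$trained,
    tag = model$tag)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- payload$spec
  spec <- predictor_spec(architecture = s$architecture, L = s$L,
                         hidden = s$hidden, kernel_size = s$kernel_size,
                         filters = s$filters, channels = s$channels,
                         adjacency = s$adjacency, seed = s$seed,
                         learning_rate = s$learning_rate, epochs = s$epochs,
                         batch_size = s$batch_size, patience = s$patience)
  model <- build_model(spec)
  ref <- model$params
  model$params <- lapply(names(ref), function(nm) {
    p <- payload$params[[nm]]
    if (is.matrix(ref[[nm]]) && !is.matrix(p)) {
      p <- matrix(p, nrow = nrow(ref[[nm]]), ncol = ncol(ref[[nm]]))
    } else if (is.matrix(p)) {
      dim(p) <- dim(ref[[nm]])
    }
    p
  })
  names(model$params) <- names(ref)
  model$history <- payload$history
  model$trained <- isTRUE(payload$trained)
  model$tag <- payload$tag
  model
}
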