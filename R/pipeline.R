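# End-to-end pipeline: featurize a model file, score it with a trained
# backbone (regression mode) or backbone embedding + energy-model grid
# inference (ebm mode), train either stage from a decoy directory, and
# evaluate prediction tables. Checkpoints carry their config so stages
# refuse mismatched inputs.

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS archives holding the model object (config +
#' weights) plus a format version; loading validates both.
#'
#' @param object a `meqa_backbone` or `meqa_ebm`
#' @param path file path
#' @return `path` invisibly / the restored object
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, c("meqa_backbone", "meqa_ebm")))
  saveRDS(list(version = CHECKPOINT_VERSION,
               class = class(object)[1L], object = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!is.list(ck) || !identical(ck$version, CHECKPOINT_VERSION)) {
    stop("incompatible checkpoint version in ", path)
  }
  ck$object
}

#' Parse and featurize one model file
#'
#' @param path PDB file
#' @param providers feature providers
#' @param cutoff contact cutoff in Angstrom
#' @return list with `structure`, `graph`, and `input` ([graph_input()])
#' @export
featurize_model <- function(path, providers = default_providers(),
                            cutoff = 8.0) {
  s <- parse_structure(path)
  g <- build_graph(s, cutoff)
  nx <- assemble_node_features(s, providers)
  ex <- assemble_edge_features(g, s, providers)
  list(structure = s, graph = g, input = graph_input(g, nx, ex))
}

#' Score model structures
#'
#' For each input: parse, build the contact graph, featurize, then either
#' predict directly with the backbone (`mode = "regression"`) or feed the
#' backbone's global embedding to the energy model and run grid inference
#' (`mode = "ebm"`).
#'
#' @param paths PDB files
#' @param backbone a trained `meqa_backbone`
#' @param ebm a trained `meqa_ebm` (required for `mode = "ebm"`)
#' @param mode `"regression"` or `"ebm"`
#' @param providers feature providers (must match those used in training)
#' @param cutoff contact cutoff
#' @param out_tsv optional TSV output path
#' @return data.frame with `model_id`, `score_type`, `mode`, `prediction`
#' @export
score_models <- function(paths, backbone, ebm = NULL,
                         mode = c("regression", "ebm"),
                         providers = default_providers(), cutoff = 8.0,
                         out_tsv = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(backbone, "meqa_backbone"))
  if (mode == "ebm") {
    if (is.null(ebm)) stop("ebm mode needs a trained energy model")
    stopifnot(inherits(ebm, "meqa_ebm"))
    if (ebm$embed_dim != backbone$config$hidden) {
      stop("energy-model embedding width (", ebm$embed_dim,
           ") does not match backbone hidden width (",
           backbone$config$hidden, ")")
    }
  }
  rows <- lapply(paths, function(p) {
    fm <- featurize_model(p, providers, cutoff)
    if (ncol(fm$input$node_x) != backbone$node_dim) {
      stop("feature width ", ncol(fm$input$node_x),
           " does not match backbone checkpoint (", backbone$node_dim, ")")
    }
    pr <- predict.meqa_backbone(backbone, fm$input)
    val <- if (mode == "regression") pr$score else
      grid_inference(ebm, pr$embedding)
    data.frame(model_id = fm$structure$model_id,
               score_type = backbone$config$score_type,
               mode = mode, prediction = val)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_tsv)) {
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Compute global embeddings for a set of graphs
#'
#' @param backbone a `meqa_backbone`
#' @param graphs list of [graph_input()]
#' @return matrix (length(graphs) x hidden)
#' @export
embed_graphs <- function(backbone, graphs) {
  t(vapply(graphs, function(g) {
    drop(predict.meqa_backbone(backbone, g)$embedding)
  }, numeric(backbone$config$hidden)))
}

# Read a decoy directory (PDBs + labels.tsv) into graph inputs + labels.
read_decoy_dir <- function(dir, score_type,
                           providers = default_providers(),
                           cutoff = 8.0) {
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) stop("no labels.tsv in ", dir)
  lab <- utils::read.delim(lab_path)
  col <- paste0(score_type, "_label")
  if (!col %in% names(lab)) stop("labels.tsv lacks column ", col)
  graphs <- list(); labels <- numeric(0); ids <- character(0)
  for (k in seq_len(nrow(lab))) {
    p <- file.path(dir, paste0(lab$model_id[k], ".pdb"))
    if (!file.exists(p)) stop("missing decoy file ", p)
    fm <- featurize_model(p, providers, cutoff)
    graphs[[k]] <- fm$input
    labels[k] <- min(max(lab[[col]][k], 1e-3), 1 - 1e-3)
    ids[k] <- lab$model_id[k]
  }
  list(graphs = graphs, labels = labels, model_id = ids)
}

#' Train a backbone from a decoy directory
#'
#' Two-stage contract, stage one: fits a backbone on the decoy structures
#' and their stand-in labels, writes the checkpoint and a CSV training
#' log next to it.
#'
#' @param dir directory with PDB decoys and labels.tsv
#' @param checkpoint output checkpoint path
#' @param config a [backbone_config()]
#' @param epochs,lr,seed training settings
#' @param providers feature providers
#' @return the trained backbone, invisibly
#' @export
train_backbone_files <- function(dir, checkpoint,
                                 config = backbone_config(),
                                 epochs = 20L, lr = 1e-3, seed = 1L,
                                 providers = default_providers()) {
  ds <- read_decoy_dir(dir, config$score_type, providers)
  bb <- new_backbone(config, node_dim = ncol(ds$graphs[[1L]]$node_x),
                     seed = seed)
  bb <- train_backbone(bb, ds$graphs, ds$labels, epochs = epochs, lr = lr,
                       seed = seed)
  save_checkpoint(bb, checkpoint)
  utils::write.csv(bb$log, paste0(checkpoint, ".log.csv"),
                   row.names = FALSE)
  invisible(bb)
}

#' Train an energy model from a decoy directory and a backbone checkpoint
#'
#' Two-stage contract, stage two: requires the pretrained backbone (its
#' embeddings are the energy model's inputs); errors with guidance when
#' the checkpoint is missing.
#'
#' @param dir directory with PDB decoys and labels.tsv
#' @param backbone_checkpoint checkpoint from [train_backbone_files()]
#' @param checkpoint output checkpoint path
#' @param cfg an [ebm_config()]
#' @param epochs,lr,seed training settings
#' @param providers feature providers
#' @return the trained `meqa_ebm`, invisibly
#' @export
train_ebm_files <- function(dir, backbone_checkpoint, checkpoint,
                            cfg = ebm_config(), epochs = 20L, lr = 1e-3,
                            seed = 1L, providers = default_providers()) {
  if (!file.exists(backbone_checkpoint)) {
    stop("backbone checkpoint not found: ", backbone_checkpoint,
         " -- train the backbone first (stage one), then the energy model")
  }
  bb <- load_checkpoint(backbone_checkpoint)
  stopifnot(inherits(bb, "meqa_backbone"))
  ds <- read_decoy_dir(dir, bb$config$score_type, providers)
  X <- embed_graphs(bb, ds$graphs)
  net <- new_ebm(cfg, embed_dim = ncol(X), seed = seed)
  net <- train_ebm(net, X, ds$labels, epochs = epochs, lr = lr,
                   seed = seed)
  save_checkpoint(net, checkpoint)
  utils::write.csv(net$log, paste0(checkpoint, ".log.csv"),
                   row.names = FALSE)
  invisible(net)
}

#' Evaluate prediction tables and write a leaderboard
#'
#' @param pred_path TSV/CSV with target_id, predictor, model_id,
#'   predicted_score
#' @param truth_path TSV/CSV with target_id, model_id, true_score
#' @param metric ordering metric for [leaderboard()]
#' @param out_csv optional output path
#' @return the leaderboard data.frame
#' @export
evaluate_tables <- function(pred_path, truth_path,
                            metric = c("loss", "ndcg3"), out_csv = NULL) {
  metric <- match.arg(metric)
  read_any <- function(p) {
    sep <- if (grepl("\\.csv$", p)) "," else "\t"
    utils::read.table(p, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  }
  pred <- read_any(pred_path)
  truth <- read_any(truth_path)
  lb <- leaderboard(pred, truth, metric = metric)
  if (!is.null(out_csv)) utils::write.csv(lb, out_csv, row.names = FALSE)
  lb
}

#' Read a run configuration
#'
#' YAML key/value file merged with overrides (overrides win); the
#' resolved configuration is reported on stderr so every run logs its
#' settings.
#'
#' @param path YAML file (optional)
#' @param overrides named list taking precedence
#' @return named list
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (length(cfg)) {
    message("resolved config: ",
            paste(names(cfg), unlist(lapply(cfg, format)), sep = "=",
                  collapse = " "))
  }
  cfg
}
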