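#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one serializable
#' list: input paths (or in-memory layers), similarity options, autoencoder
#' settings, forest parameters, cross-validation protocol and seeds. The
#' configuration is embedded in every artifact [run_pipeline()] writes, and
#' artifacts carry its checksum, so a run can be traced back to its exact
#' settings.
#'
#' @param ld,lm,md paths to the three layer files (dense labeled CSV/TSV) or
#'   `bipartite_adjacency` objects.
#' @param latent_dim,lambda_tilde,jaccard_denominator,similarity_source,epochs,batch_size,learning_rate,ntree,mtry,seed
#'   see [gclda_fit()].
#' @param k,strict,per_fold_negatives,pooled see [gclda_cv()].
#' @param top_n number of globally top-ranked candidate pairs to report.
#' @return a list of class `gclda_config`.
#' @export
gclda_config <- function(ld, lm, md, latent_dim = 256, lambda_tilde = 1,
                         jaccard_denominator = "union",
                         similarity_source = "original",
                         epochs = 200, batch_size = 32, learning_rate = 1e-3,
                         ntree = 500, mtry = NULL, seed = 1,
                         k = 5, strict = FALSE, per_fold_negatives = FALSE,
                         pooled = FALSE, top_n = 20) {
  structure(list(ld = ld, lm = lm, md = md, latent_dim = latent_dim,
                 lambda_tilde = lambda_tilde,
                 jaccard_denominator = jaccard_denominator,
                 similarity_source = similarity_source, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 ntree = ntree, mtry = mtry, seed = seed, k = k,
                 strict = strict, per_fold_negatives = per_fold_negatives,
                 pooled = pooled, top_n = top_n),
            class = "gclda_config")
}

#' Run the full pipeline and write its artifacts
#'
#' Executes complement -> similarities -> fusion -> raw features ->
#' autoencoders -> balanced samples -> forest -> cross-validation -> global
#' candidate ranking, writing every intermediate artifact (dense labeled
#' CSVs, the evaluation report as JSON, rankings as TSV) plus a structured
#' log to `outdir`. Identical configurations reproduce identical artifacts.
#'
#' @param config a [gclda_config()].
#' @param outdir output directory; `NULL` skips writing.
#' @return list with the fitted `gclda` model, the `gclda_cv` report and the
#'   ranked predictions, invisibly when writing.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "gclda_config"))
  load_layer <- function(x, rk, ck) {
    if (inherits(x, "bipartite_adjacency")) x
    else read_adjacency(x, "dense", rk, ck)
  }
  log_lines <- character()
  stamp <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  LD <- step("load", load_layer(config$ld, "lncRNA", "disease"))
  LM <- step("load", load_layer(config$lm, "lncRNA", "miRNA"))
  MD <- step("load", load_layer(config$md, "miRNA", "disease"))
  stamp("load", sprintf("%d lncRNAs, %d miRNAs, %d diseases",
                        nrow(LD), ncol(LM), ncol(LD)))

  fit <- step("fit", gclda_fit(
    LD, LM, MD, latent_dim = config$latent_dim,
    lambda_tilde = config$lambda_tilde,
    jaccard_denominator = config$jaccard_denominator,
    similarity_source = config$similarity_source, epochs = config$epochs,
    batch_size = config$batch_size, learning_rate = config$learning_rate,
    ntree = config$ntree, mtry = config$mtry, seed = config$seed))
  stamp("fit", sprintf("%d zero-evidence complement cells",
                       sum(fit$comp$lmd == 0 & fit$comp$ld == 0)))

  report <- step("cv", gclda_cv(fit, k = config$k, seed = config$seed,
                                strict = config$strict,
                                per_fold_negatives = config$per_fold_negatives,
                                pooled = config$pooled))
  stamp("cv", sprintf("mean AUC %.4f, AUPR %.4f",
                      report$mean_metrics[["auc"]],
                      report$mean_metrics[["aupr"]]))

  ranking <- step("rank", predict(fit, top_n = config$top_n))
  result <- list(fit = fit, report = report, ranking = ranking,
                 config = config)
  if (is.null(outdir)) return(result)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  cfg_ser <- config
  for (nm in c("ld", "lm", "md"))
    if (!is.character(cfg_ser[[nm]])) cfg_ser[[nm]] <- "<in-memory>"
  cfg_json <- .to_json(unclass(cfg_ser))
  writeLines(cfg_json, fp("config.json"))
  hash <- unname(tools::md5sum(fp("config.json")))

  write_matrix_csv(fit$comp$lmd, fp("lmd.csv"))
  write_matrix_csv(fit$comp$ld_new, fp("ld_new.csv"))
  write_matrix_csv(unclass(fit$lfj), fp("lfj.csv"))
  write_matrix_csv(unclass(fit$dsj), fp("dsj.csv"))
  write_matrix_csv(fit$lnc_enc, fp("lnc_encoded.csv"))
  write_matrix_csv(fit$dis_enc, fp("dis_encoded.csv"))
  utils::write.table(cbind(config_hash = hash, round(report$fold_metrics, 6)),
                     fp("fold_metrics.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  writeLines(.to_json(list(
    config_hash = hash,
    protocol = report$leakage,
    mean_metrics = as.list(report$mean_metrics),
    fold_metrics = report$fold_metrics)), fp("report.json"))
  utils::write.table(report$roc, fp("roc_points.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$pr, fp("pr_points.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ranking, fp("ranking.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stamp("write", sprintf("artifacts in %s (config %s)", outdir, hash))
  writeLines(log_lines, fp("run.log"))
  invisible(result)
}

# Labeled dense CSV writer used for all real-valued artifact matrices.
write_matrix_csv <- function(m, path) {
  df <- data.frame(name = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- ""
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal JSON serializer for flat config/report lists (jsonlite is only
# suggested; artifacts must not depend on it).
.to_json <- function(x) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.data.frame(v))
      return(paste0("[", paste(vapply(seq_len(nrow(v)), function(i)
        enc(as.list(v[i, , drop = FALSE])), ""), collapse = ","), "]"))
    if (is.list(v))
      return(paste0("{", paste(sprintf("\"%s\":%s", names(v),
                                       vapply(v, enc, "")), collapse = ","),
                    "}"))
    if (length(v) != 1L)
      return(paste0("[", paste(vapply(v, enc, ""), collapse = ","), "]"))
    if (is.character(v)) sprintf("\"%s\"", gsub("\"", "\\\\\"", v))
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  enc(x)
}

#' Sweep autoencoder latent dimensions
#'
#' Re-runs the representation and prediction stages over a grid of lncRNA
#' and disease latent dimensions, reporting the mean cross-validated AUC per
#' cell. The complement, similarities and raw features are computed once and
#' shared across cells. A dimension that is not smaller than the raw feature
#' width invalidates its cells (recorded as `NA` with a reason) without
#' stopping the sweep.
#'
#' @param config a [gclda_config()]; its `latent_dim` is ignored.
#' @param lnc_dims,dis_dims integer vectors of latent widths to try.
#' @return list with `auc` (matrix, rows = lnc_dims, cols = dis_dims) and
#'   `invalid` (data.frame of skipped cells and reasons).
#' @export
run_dimension_sweep <- function(config, lnc_dims, dis_dims = lnc_dims) {
  stopifnot(inherits(config, "gclda_config"))
  auc <- matrix(NA_real_, length(lnc_dims), length(dis_dims),
                dimnames = list(lnc_dims, dis_dims))
  invalid <- data.frame(lnc_dim = integer(), dis_dim = integer(),
                        reason = character())
  for (i in seq_along(lnc_dims)) for (j in seq_along(dis_dims)) {
    cfg <- config
    cfg$latent_dim <- c(lnc_dims[i], dis_dims[j])
    res <- tryCatch(run_pipeline(cfg, outdir = NULL),
                    error = function(e) e)
    if (inherits(res, "error")) {
      invalid <- rbind(invalid, data.frame(
        lnc_dim = lnc_dims[i], dis_dim = dis_dims[j],
        reason = conditionMessage(res)))
    } else {
      auc[i, j] <- res$report$mean_metrics[["auc"]]
    }
  }
  list(auc = auc, invalid = invalid)
}
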