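#' Pipeline configuration
#'
#' Bundles inputs, comparisons and thresholds for [run_pipeline()]. Inputs
#' may be file paths (TSV/GMT, read with the package readers) or in-memory
#' objects from [simulate_experiment()] / [simulate_annotation()].
#'
#' @param counts_total,counts_polysome Count matrix paths or
#'   [count_matrix()] objects.
#' @param sample_sheet Sample sheet path or data.frame.
#' @param annotation Optional GMT path or `AnnotationDB` for enrichment.
#' @param comparisons List of `c(condition_b, condition_a)` pairs; each is
#'   reported as `"B_vs_A"`. Defaults to the six pairwise comparisons of
#'   the four-condition design.
#' @param lfc_threshold,alpha Classification thresholds (default 1, 0.05).
#' @param min_count,min_samples Low-expression filter (default 10 in >= 2
#'   samples).
#' @param min_module_size,cut_height Module detection parameters.
#' @param jaccard_threshold Cross-level relatedness threshold (default
#'   0.05).
#' @param term_size_max,intersection_min Enrichment filters (default 250,
#'   10).
#' @param outdir Output directory.
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic).
#' @param figures Write figure files (requires pheatmap for heatmaps).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(counts_total, counts_polysome, sample_sheet,
                            annotation = NULL,
                            comparisons = list(
                              c("Combo", "Control"),
                              c("Combo", "Hardening"),
                              c("Combo", "Stress"),
                              c("Hardening", "Control"),
                              c("Stress", "Control"),
                              c("Stress", "Hardening")),
                            lfc_threshold = 1, alpha = 0.05,
                            min_count = 10, min_samples = 2,
                            min_module_size = 30, cut_height = 0.99,
                            jaccard_threshold = 0.05,
                            term_size_max = 250, intersection_min = 10,
                            outdir = "translevel_out", seed = 1,
                            figures = FALSE) {
  cfg <- as.list(environment())
  stopifnot(lfc_threshold > 0, alpha > 0, alpha < 1,
            jaccard_threshold >= 0, jaccard_threshold <= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()] (comparisons as a list of two-element lists).
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$comparisons))
    y$comparisons <- lapply(y$comparisons, unlist)
  do.call(pipeline_config, y)
}

resolve_counts <- function(x, fraction) {
  if (inherits(x, "CountMatrix")) x else read_counts(x, fraction)
}

resolve_sheet <- function(x) {
  if (is.data.frame(x)) validate_sample_sheet(as.data.frame(x))
  else read_sample_sheet(x)
}

pipe_log <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full two-level analysis
#'
#' Executes, in order: load, collapse of technical replicates,
#' low-expression filtering (genes must pass in both fractions), PCA
#' overview of all samples, per-comparison differential expression in each
#' fraction with Up/Down/Stable classification, translational ratios and
#' per-comparison differential translation (interaction test), UpSet
#' exclusive intersections and Jaccard matrices of the class sets at both
#' levels, stable-core extraction, weighted co-expression module detection
#' at both levels with module-trait correlations and hub genes,
#' cross-level module overlap, and (when an annotation is supplied)
#' over-representation analysis of the Up/Down sets. Every table is
#' written as TSV under `outdir` and listed, with an MD5 checksum, in
#' `manifest.json`. Identical inputs and config yield identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run.log")
  cat("", file = log_path)
  set.seed(cfg$seed)
  outputs <- character()
  stage <- function(name, expr) {
    pipe_log(log_path, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- load & collapse
  res <- list()
  stage("load", {
    total <- resolve_counts(cfg$counts_total, "total")
    poly <- resolve_counts(cfg$counts_polysome, "polysome")
    ss <- resolve_sheet(cfg$sample_sheet)
    ann <- if (is.null(cfg$annotation)) NULL
    else if (inherits(cfg$annotation, "AnnotationDB")) cfg$annotation
    else read_gmt(cfg$annotation)
    res$annotation <- ann
    res$total_raw <- total; res$poly_raw <- poly; res$sheet <- ss
  })
  stage("collapse", {
    res$total <- collapse_technical_replicates(res$total_raw, res$sheet)
    res$poly <- collapse_technical_replicates(res$poly_raw, res$sheet)
  })
  stage("filter", {
    keep_t <- rownames(filter_low_expression(res$total, cfg$min_count,
                                             cfg$min_samples)$counts)
    keep_p <- rownames(filter_low_expression(res$poly, cfg$min_count,
                                             cfg$min_samples)$counts)
    keep <- intersect(keep_t, keep_p)
    res$total <- count_matrix(res$total$counts[keep, , drop = FALSE], "total")
    res$poly <- count_matrix(res$poly$counts[keep, , drop = FALSE],
                              "polysome")
    pipe_log(log_path, length(keep), " genes pass the expression filter")
  })
  sheet_c <- rbind(
    data.frame(attr(collapse_technical_replicates(res$total_raw, res$sheet),
                    "sample_sheet"), stringsAsFactors = FALSE),
    data.frame(attr(collapse_technical_replicates(res$poly_raw, res$sheet),
                    "sample_sheet"), stringsAsFactors = FALSE))

  # --- PCA overview over all collapsed samples, both fractions
  stage("pca", {
    both <- count_matrix(cbind(res$total$counts, res$poly$counts), "mixed")
    nm <- cpm_normalize(both, log = TRUE, pseudocount = 1)
    p <- pca_overview(nm, n_components = min(4, ncol(both$counts)))
    coords <- data.frame(sample_id = rownames(p$coordinates),
                         p$coordinates,
                         explained = c(p$explained_variance,
                                       rep(NA, max(0, ncol(p$coordinates) -
                                                     length(p$explained_variance)))))
    outputs <- c(outputs, write_tsv(coords, file.path(cfg$outdir, "pca.tsv")))
    res$pca <- p
  })

  cond_of <- function(cm) sheet_c$condition[match(colnames(cm$counts),
                                                  sheet_c$sample_id)]
  cmp_name <- function(cc) paste0(cc[1], "_vs_", cc[2])

  # --- differential expression per fraction per comparison
  stage("differential_expression", {
    res$de <- list()
    for (fr in c("total", "polysome")) {
      cm <- if (fr == "total") res$total else res$poly
      conds <- cond_of(cm)
      for (cc in cfg$comparisons) {
        de <- test_differential(cm,
                                group_a = which(conds == cc[2]),
                                group_b = which(conds == cc[1]))
        de <- classify_genes(de, cfg$lfc_threshold, cfg$alpha)
        nm <- paste0(cmp_name(cc), if (fr == "total") "_T" else "_P")
        res$de[[nm]] <- de
        outputs <- c(outputs, write_tsv(
          de[, c("gene_id", "logFC", "PValue", "FDR", "class")],
          file.path(cfg$outdir, paste0("de_", nm, ".tsv"))))
      }
    }
  })

  # --- translational ratio and differential translation
  stage("translation", {
    tot_nm <- cpm_normalize(res$total)
    pol_nm <- cpm_normalize(res$poly)
    res$tr <- translational_ratio(tot_nm, pol_nm, sheet_c)
    tr_df <- data.frame(gene_id = rownames(res$tr$values), res$tr$values,
                        check.names = FALSE)
    outputs <- c(outputs, write_tsv(tr_df, file.path(cfg$outdir, "tr.tsv")))
    res$dtr <- list()
    for (cc in cfg$comparisons) {
      dt <- test_differential_translation(res$total, res$poly, sheet_c,
                                          condition_a = cc[2],
                                          condition_b = cc[1],
                                          lfc_threshold = cfg$lfc_threshold,
                                          alpha = cfg$alpha)
      res$dtr[[cmp_name(cc)]] <- dt
      outputs <- c(outputs, write_tsv(
        dt[, c("gene_id", "deltaTR", "PValue", "FDR", "class")],
        file.path(cfg$outdir, paste0("dtr_", cmp_name(cc), ".tsv"))))
    }
  })

  # --- set comparison per level and class
  stage("set_comparison", {
    res$sets <- list()
    for (lev in c("T", "P", "TR")) {
      for (cls in c("Up", "Down", "Stable")) {
        sets <- list()
        for (cc in cfg$comparisons) {
          nm <- cmp_name(cc)
          tab <- if (lev == "TR") res$dtr[[nm]] else res$de[[paste0(nm, "_", lev)]]
          sets[[paste0(nm, "_", lev)]] <- tab$gene_id[tab$class == cls]
        }
        res$sets[[paste0(lev, "_", cls)]] <- sets
        up <- upset_intersections(sets)
        J <- jaccard_matrix(sets)
        tag <- paste0(lev, "_", cls)
        outputs <- c(outputs,
          write_tsv(up[, c("combination", "degree", "size")],
                    file.path(cfg$outdir, paste0("upset_", tag, ".tsv"))),
          write_tsv(data.frame(set = rownames(J), J, check.names = FALSE),
                    file.path(cfg$outdir, paste0("jaccard_", tag, ".tsv"))))
      }
    }
    core <- stable_core(res$sets$TR_Stable)
    res$stable_core <- core
    outputs <- c(outputs, write_tsv(data.frame(gene_id = core),
                                     file.path(cfg$outdir, "stable_core.tsv")))
    pipe_log(log_path, "stable core: ", length(core), " genes")
  })

  # --- co-expression networks at both levels
  stage("coexpression", {
    res$wgcna <- list()
    inputs <- list(
      transcription = cpm_normalize(res$total, log = TRUE, pseudocount = 1),
      translation = {
        tot_nm <- cpm_normalize(res$total)
        pol_nm <- cpm_normalize(res$poly)
        tr_rep <- translational_ratio(tot_nm, pol_nm, sheet_c,
                                      per = "replicate")
        renorm <- tr_normalize_million(tr_rep)
        normalized_matrix(log2(renorm$values + 1), "log2cpm", 1)
      })
    for (lev in names(inputs)) {
      nm <- inputs[[lev]]
      v <- nm$values[row_vars(nm$values) > 0, , drop = FALSE]
      st <- suppressWarnings(pick_soft_threshold(v))
      net <- adjacency(v, beta = st$beta)
      tom <- topological_overlap(net)
      ma <- detect_modules(tom, cfg$min_module_size, cfg$cut_height)
      eg <- module_eigengene(v, ma)
      traits <- if (lev == "transcription") {
        conds <- cond_of(res$total)
        stats::model.matrix(~ 0 + conds)
      } else {
        cnd <- sub("_.*$", "", colnames(v))
        stats::model.matrix(~ 0 + cnd)
      }
      colnames(traits) <- sub("^(conds|cnd)", "", colnames(traits))
      rownames(traits) <- colnames(v)
      mt <- if (nrow(eg) > 0) module_trait_correlation(eg, traits) else NULL
      hubs <- if (nrow(eg) > 0) hub_genes(v, ma, eg) else NULL
      res$wgcna[[lev]] <- list(beta = st$beta, low_fit = st$low_fit,
                                modules = ma, eigengenes = eg,
                                module_trait = mt, hubs = hubs)
      outputs <- c(outputs, write_tsv(
        data.frame(gene_id = names(ma$labels), module = unname(ma$labels)),
        file.path(cfg$outdir, paste0("modules_", lev, ".tsv"))))
      if (!is.null(mt))
        outputs <- c(outputs, write_tsv(mt, file.path(
          cfg$outdir, paste0("module_trait_", lev, ".tsv"))))
      if (!is.null(hubs))
        outputs <- c(outputs, write_tsv(hubs, file.path(
          cfg$outdir, paste0("hub_genes_", lev, ".tsv"))))
      pipe_log(log_path, lev, ": beta=", st$beta, ", ",
               length(ma$sizes) - 1, " modules")
    }
  })

  # --- cross-level module overlap
  stage("crosslevel", {
    ma_t <- res$wgcna$transcription$modules
    ma_p <- res$wgcna$translation$modules
    if (length(ma_t$sizes) > 1 && length(ma_p$sizes) > 1) {
      ov <- module_overlap(ma_t, ma_p, cfg$jaccard_threshold, cfg$alpha)
      res$crosslevel <- ov
      outputs <- c(outputs, write_tsv(ov, file.path(cfg$outdir,
                                                     "crosslevel.tsv")))
      pipe_log(log_path, sum(ov$related), " related module pair(s)")
    } else {
      pipe_log(log_path, "crosslevel skipped: a level has no modules")
    }
  })

  # --- enrichment of Up/Down sets (transcription and translation levels)
  stage("enrichment", {
    if (!is.null(res$annotation)) {
      universe <- rownames(res$total$counts)
      enr_rows <- list()
      for (tag in names(res$sets)) {
        if (grepl("_Stable$", tag)) next
        for (snm in names(res$sets[[tag]])) {
          qry <- intersect(res$sets[[tag]][[snm]], universe)
          if (length(qry) < cfg$intersection_min) next
          e <- enrich(qry, res$annotation, universe,
                      cfg$term_size_max, cfg$intersection_min)
          if (nrow(e)) {
            e$query <- snm
            enr_rows[[length(enr_rows) + 1L]] <- e
          }
        }
      }
      if (length(enr_rows)) {
        enr <- do.call(rbind, enr_rows)
        res$enrichment <- enr
        outputs <- c(outputs, write_tsv(enr, file.path(cfg$outdir,
                                                        "enrichment.tsv")))
      }
    } else pipe_log(log_path, "enrichment skipped: no annotation")
  })

  if (isTRUE(cfg$figures)) stage("figures", {
    figs <- write_pipeline_figures(res, cfg)
    pipe_log(log_path, length(figs), " figure(s) written")
  })

  # --- manifest
  stage("manifest", {
    manifest <- list(
      package = "translevel",
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), c("counts_total", "counts_polysome",
                                         "sample_sheet", "annotation"))],
      n_genes = nrow(res$total$counts),
      outputs = lapply(sort(outputs), function(f) list(
        file = basename(f), md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  })
  pipe_log(log_path, "done: ", length(outputs), " tables in ", cfg$outdir)
  invisible(res)
}
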