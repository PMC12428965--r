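#' Configuration for the synthetic two-level experiment
#'
#' Describes a paired total/polysome count experiment with planted
#' transcriptional programs, translational programs, a stable core and
#' co-expression modules. Defaults mirror the design of the cold-stress
#' study the package targets: four conditions (Control, Hardening, Stress,
#' Combo), two fractions, two technical repeats per library, NB-distributed
#' counts, with Hardening and Combo sharing most of their transcriptional
#' program while Stress acts mainly at the translational level.
#'
#' @param n_genes Number of genes (default 2000).
#' @param conditions Condition names; the first is the reference with zero
#'   effects.
#' @param n_bio_replicates Biological replicates per condition (default 3).
#' @param n_tech_replicates Technical repeats per library (default 2),
#'   generated by binomially thinning one latent library.
#' @param library_size_mean,library_size_sdlog Log-normal library sizes
#'   (per technical repeat; default mean 5e6, sdlog 0.1).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline log2
#'   abundance, CPM-scale realism (default N(6, 2)).
#' @param base_te_log2_sd Per-gene baseline translational-ratio spread on
#'   log2 (default 0.5).
#' @param phi NB dispersion (default 0.1).
#' @param n_transcription_up,n_transcription_down Named integer vectors
#'   (per non-reference condition) of transcriptionally regulated genes.
#' @param n_translation_up,n_translation_down Same for translational
#'   programs.
#' @param transcription_effect,translation_effect Planted effect sizes in
#'   log2 (default 2, i.e. 4-fold).
#' @param combo_share Fraction of the Combo transcriptional program shared
#'   with Hardening (default 0.8; ignored unless both are present).
#' @param n_stable_core Genes guaranteed free of any planted effect and of
#'   module membership (default 150).
#' @param n_modules,module_size,module_strength Planted co-expression
#'   modules: count, genes per module, and log2-scale loading of the
#'   shared latent factor (default 3 x 50 at strength 0.8).
#' @param module_types Character vector (recycled over modules):
#'   `"transcription"` loads the factor equally on both fractions, so the
#'   module is visible in total-RNA expression but cancels out of the
#'   translational ratio; `"translation"` loads it on the polysome
#'   fraction only, so the module lives in the translational ratio;
#'   `"both"` loads total once and polysome twice, leaving the module
#'   visible at both levels.
#' @param seed Integer seed; the simulation is deterministic given the
#'   config.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              conditions = c("Control", "Hardening",
                                             "Stress", "Combo"),
                              n_bio_replicates = 3,
                              n_tech_replicates = 2,
                              library_size_mean = 5e6,
                              library_size_sdlog = 0.1,
                              baseline_log2_mean = 6,
                              baseline_log2_sd = 2,
                              base_te_log2_sd = 0.5,
                              phi = 0.1,
                              n_transcription_up = c(Hardening = 150,
                                                     Stress = 30,
                                                     Combo = 150),
                              n_transcription_down = c(Hardening = 150,
                                                       Stress = 30,
                                                       Combo = 150),
                              n_translation_up = c(Hardening = 30,
                                                   Stress = 150,
                                                   Combo = 100),
                              n_translation_down = c(Hardening = 30,
                                                     Stress = 150,
                                                     Combo = 100),
                              transcription_effect = 2,
                              translation_effect = 2,
                              combo_share = 0.8,
                              n_stable_core = 150,
                              n_modules = 3,
                              module_size = 50,
                              module_strength = 0.8,
                              module_types = c("transcription", "translation"),
                              seed = 1) {
  cfg <- as.list(environment())
  prune <- function(v) v[names(v) %in% conditions[-1] & v > 0]
  cfg$n_transcription_up <- prune(n_transcription_up)
  cfg$n_transcription_down <- prune(n_transcription_down)
  cfg$n_translation_up <- prune(n_translation_up)
  cfg$n_translation_down <- prune(n_translation_down)
  stopifnot(n_genes > 0, n_bio_replicates >= 1, n_tech_replicates >= 1,
            phi >= 0, length(conditions) >= 2, n_stable_core >= 0,
            n_modules >= 0, module_size > 0, module_strength >= 0,
            all(module_types %in% c("transcription", "translation", "both")))
  cfg$module_types <- if (n_modules > 0)
    rep_len(module_types, n_modules) else character()
  trans_total <- max(c(0, cfg$n_transcription_up + cfg$n_transcription_down[
    names(cfg$n_transcription_up)]), na.rm = TRUE)
  budget <- n_stable_core + n_modules * module_size +
    max(0, max(c(cfg$n_transcription_up, 0)) + max(c(cfg$n_transcription_down, 0))) +
    max(0, max(c(cfg$n_translation_up, 0)) + max(c(cfg$n_translation_down, 0)))
  if (budget > n_genes)
    stop("planted program sizes exceed n_genes")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a paired total/polysome experiment
#'
#' Total-fraction expected abundance is `baseline * 2^transcription_effect`
#' per condition; the polysome-fraction abundance additionally carries the
#' gene's baseline translational ratio and any planted translational
#' effect. Module genes share a per-biological-sample latent factor on the
#' log2-mean scale (common to both fractions). Counts are NB-distributed
#' around expected proportions times a log-normal latent library size;
#' technical repeats are binomially thinned halves of the latent library,
#' reflecting resequencing of one library rather than independent biology.
#'
#' @param cfg A [simulation_config()].
#' @return List with `total` and `polysome` ([count_matrix()]),
#'   `sample_sheet`, and `truth` (a `GroundTruth` data.frame with the
#'   planted per-gene transcriptional/translational effects per condition,
#'   stable-core flag and module id).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  conds <- cfg$conditions
  genes <- sprintf("g%04d", seq_len(ng))

  # --- gene role allocation: core, modules, then programs from the rest
  pool <- seq_len(ng)
  core <- utils::head(pool, cfg$n_stable_core)
  pool <- setdiff(pool, core)
  module_id <- rep(NA_character_, ng)
  if (cfg$n_modules > 0) {
    for (m in seq_len(cfg$n_modules)) {
      take <- utils::head(pool, cfg$module_size)
      module_id[take] <- sprintf("M%d", m)
      pool <- setdiff(pool, take)
    }
  }
  E <- matrix(0, ng, length(conds), dimnames = list(genes, conds))
  Tm <- matrix(0, ng, length(conds), dimnames = list(genes, conds))
  draw <- function(n, from) {
    if (n > length(from)) stop("planted program sizes exceed available genes")
    if (n == length(from)) from else sample(from, n)
  }
  # Transcription programs are disjoint across conditions, except that
  # Combo deliberately re-uses a share of Hardening's program (hardened
  # plants keep their reprogrammed transcriptome when stressed).
  pool_t <- pool
  prog_t <- list()
  for (dir in c("up", "down")) {
    nn <- if (dir == "up") cfg$n_transcription_up else cfg$n_transcription_down
    for (cn in names(nn)) {
      shared <- integer()
      n_fresh <- nn[[cn]]
      hkey <- paste0("Hardening_", dir)
      if (cn == "Combo" && !is.null(prog_t[[hkey]])) {
        n_sh <- min(round(cfg$combo_share * nn[[cn]]),
                    length(prog_t[[hkey]]))
        shared <- sample(prog_t[[hkey]], n_sh)
        n_fresh <- nn[[cn]] - n_sh
      }
      fresh <- draw(n_fresh, pool_t)
      pool_t <- setdiff(pool_t, fresh)
      idx <- c(shared, fresh)
      prog_t[[paste0(cn, "_", dir)]] <- idx
      E[idx, cn] <- if (dir == "up") cfg$transcription_effect
      else -cfg$transcription_effect
    }
  }
  # Translation programs: disjoint across conditions and directions,
  # drawn independently of the transcriptional allocation.
  pool_l <- pool
  for (dir in c("up", "down")) {
    nn <- if (dir == "up") cfg$n_translation_up else cfg$n_translation_down
    for (cn in names(nn)) {
      idx <- draw(nn[[cn]], pool_l)
      pool_l <- setdiff(pool_l, idx)
      Tm[idx, cn] <- if (dir == "up") cfg$translation_effect
      else -cfg$translation_effect
    }
  }

  baseline <- stats::rnorm(ng, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  base_te <- stats::rnorm(ng, 0, cfg$base_te_log2_sd)

  # --- samples
  design <- expand.grid(technical_replicate = seq_len(cfg$n_tech_replicates),
                        biological_replicate = seq_len(cfg$n_bio_replicates),
                        fraction = c("total", "polysome"),
                        condition = conds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("condition", "fraction",
                       "biological_replicate", "technical_replicate")]
  design$sample_id <- with(design, paste0(condition, "_", fraction,
                                          "_b", biological_replicate,
                                          "_t", technical_replicate))
  # latent module factors per biological sample (condition x bio replicate)
  bio_keys <- unique(design[, c("condition", "biological_replicate")])
  nmod <- cfg$n_modules
  fac <- if (nmod > 0)
    matrix(stats::rnorm(nmod * nrow(bio_keys)), nmod, nrow(bio_keys))
  else matrix(0, 0, nrow(bio_keys))

  counts <- list(total = matrix(0, ng, 0), polysome = matrix(0, ng, 0))
  sheets <- list()
  for (ci in seq_along(conds)) {
    for (b in seq_len(cfg$n_bio_replicates)) {
      bk <- which(bio_keys$condition == conds[ci] &
                    bio_keys$biological_replicate == b)
      modadd_t <- modadd_p <- rep(0, ng)
      if (nmod > 0) {
        for (m in seq_len(nmod)) {
          sel <- !is.na(module_id) & module_id == sprintf("M%d", m)
          load <- cfg$module_strength * fac[m, bk]
          type <- cfg$module_types[m]
          if (type %in% c("transcription", "both")) modadd_t[sel] <- load
          modadd_p[sel] <- switch(type, transcription = load,
                                  translation = load, both = 2 * load)
        }
      }
      for (fr in c("total", "polysome")) {
        modadd <- if (fr == "total") modadd_t else modadd_p
        lg <- baseline + E[, conds[ci]] + modadd
        if (fr == "polysome") lg <- lg + base_te + Tm[, conds[ci]]
        mu_rel <- 2^lg
        p <- mu_rel / sum(mu_rel)
        latent_size <- stats::rlnorm(
          1, log(cfg$library_size_mean * cfg$n_tech_replicates),
          cfg$library_size_sdlog)
        mu <- p * latent_size
        latent <- if (cfg$phi > 0)
          stats::rnbinom(ng, mu = mu, size = 1 / cfg$phi)
        else stats::rpois(ng, mu)
        remaining <- latent
        for (tch in seq_len(cfg$n_tech_replicates)) {
          y <- if (tch == cfg$n_tech_replicates) remaining
          else stats::rbinom(ng, remaining,
                             1 / (cfg$n_tech_replicates - tch + 1))
          remaining <- remaining - y
          counts[[fr]] <- cbind(counts[[fr]], y)
          sheets[[length(sheets) + 1L]] <- data.frame(
            sample_id = paste0(conds[ci], "_", fr, "_b", b, "_t", tch),
            condition = conds[ci], fraction = fr,
            biological_replicate = b, technical_replicate = tch,
            stringsAsFactors = FALSE)
          colnames(counts[[fr]])[ncol(counts[[fr]])] <-
            sheets[[length(sheets)]]$sample_id
        }
      }
    }
  }
  for (fr in c("total", "polysome")) rownames(counts[[fr]]) <- genes
  ss <- validate_sample_sheet(do.call(rbind, sheets))

  truth <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cn in conds[-1]) {
    truth[[paste0("trans_", cn)]] <- E[, cn]
    truth[[paste0("transl_", cn)]] <- Tm[, cn]
  }
  truth$stable_core <- seq_len(ng) %in% core
  truth$module <- module_id
  truth$module_type <- ifelse(
    is.na(module_id), NA_character_,
    cfg$module_types[as.integer(sub("^M", "", module_id))])
  truth$baseline_log2 <- baseline
  truth$base_te_log2 <- base_te
  class(truth) <- c("GroundTruth", "data.frame")

  list(total = count_matrix(counts$total, "total"),
       polysome = count_matrix(counts$polysome, "polysome"),
       sample_sheet = ss,
       truth = truth)
}

#' Simulate a gene-set annotation matched to a ground truth
#'
#' Produces random background terms plus one "program term" per planted
#' regulatory program (condition x direction x level), whose members are
#' drawn mostly (`program_frac`) from the program's genes, so that
#' over-representation analysis has planted positives to find.
#'
#' @param truth A `GroundTruth` from [simulate_experiment()].
#' @param n_terms Number of random background terms (default 50).
#' @param term_size_range Inclusive size range of random terms (default
#'   c(10, 60)).
#' @param program_frac Fraction of a program term's members taken from the
#'   program itself (default 0.7).
#' @param seed Seed for the annotation draw (default 1).
#' @return An `AnnotationDB`.
#' @export
simulate_annotation <- function(truth, n_terms = 50,
                                term_size_range = c(10, 60),
                                program_frac = 0.7, seed = 1) {
  set.seed(seed)
  genes <- truth$gene_id
  sets <- list()
  desc <- character()
  for (i in seq_len(n_terms)) {
    sz <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    id <- sprintf("RAND:%04d", i)
    sets[[id]] <- sample(genes, sz)
    desc[id] <- sprintf("random background term %d", i)
  }
  eff_cols <- grep("^(trans|transl)_", colnames(truth), value = TRUE)
  for (cl in eff_cols) {
    for (dir in c("up", "down")) {
      prog <- genes[if (dir == "up") truth[[cl]] > 0 else truth[[cl]] < 0]
      if (length(prog) < 5) next
      sz <- min(length(prog), max(term_size_range))
      n_in <- ceiling(program_frac * sz)
      id <- sprintf("PROG:%s_%s", cl, dir)
      sets[[id]] <- unique(c(sample(prog, n_in),
                             sample(setdiff(genes, prog), sz - n_in)))
      desc[id] <- sprintf("planted program term: %s %s", cl, dir)
    }
  }
  structure(list(sets = sets, description = desc), class = "AnnotationDB")
}

#' Configuration of the shipped example fixture
#'
#' The package ships a small synthetic experiment under
#' `inst/extdata/synthetic_fixture/` (150 genes, 4 conditions x 2
#' fractions x 3 biological x 2 technical replicates = 48 libraries),
#' generated by [simulate_experiment()] with this configuration, so the
#' files can be regenerated bit-for-bit.
#'
#' @return The [simulation_config()] of the shipped fixture.
#' @export
fixture_config <- function() {
  simulation_config(
    n_genes = 150, n_stable_core = 20,
    n_transcription_up = c(Hardening = 15, Stress = 5, Combo = 15),
    n_transcription_down = c(Hardening = 15, Stress = 5, Combo = 15),
    n_translation_up = c(Hardening = 5, Stress = 15, Combo = 10),
    n_translation_down = c(Hardening = 5, Stress = 15, Combo = 10),
    library_size_mean = 3e5,
    n_modules = 2, module_size = 25,
    module_types = c("transcription", "translation"),
    seed = 20260901)
}

#' Write a simulated experiment as a file fixture
#'
#' Writes `counts_total.tsv`, `counts_polysome.tsv`, `sample_sheet.tsv`,
#' `truth.tsv` and, when an annotation is supplied, `annotation.gmt` into
#' `dir`, in the same formats the rest of the pipeline reads.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @param annotation Optional `AnnotationDB`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$total, file.path(dir, "counts_total.tsv"))
  write_counts(sim$polysome, file.path(dir, "counts_polysome.tsv"))
  write_sample_sheet(sim$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  utils::write.table(as.data.frame(sim$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation))
    write_gmt(annotation, file.path(dir, "annotation.gmt"))
  invisible(dir)
}
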