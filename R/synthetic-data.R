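#' Parameters for the synthetic multi-study generator
#'
#' The generator states a concrete world: K case/control log2 expression
#' studies over a shared gene universe with a planted, downregulated DE
#' signal; shared co-expression modules so that study-quality indices have
#' structure to measure; optionally one corrupted study regenerated with no
#' shared structure; a two-group miRNA study with planted fold changes; and
#' three partially overlapping target-prediction sources.
#'
#' @param n_studies Number of mRNA studies K.
#' @param genes Genes per study G (shared universe).
#' @param n_case,n_control Samples per group per study (scalar or length-K).
#' @param de_fraction Proportion of genes with planted DE signal.
#' @param effect_size_range Planted |log2 effect| range (delta_lo, delta_hi).
#' @param direction `"down"` (default; matches the all-downregulated
#'   meta-DE pattern the workflow targets) or `"both"` (random signs).
#' @param baseline_mean,baseline_sd Gene baseline log2 level distribution.
#' @param study_batch_sd SD of the per-gene-per-study batch offset.
#' @param gene_noise_sd_range Range of the per-gene residual SD sigma_g.
#' @param n_modules,module_fraction,module_strength Optional shared
#'   co-expression modules (off by default, `module_fraction = 0`, so the
#'   default model is exactly baseline + batch + planted effect + noise):
#'   number of modules, fraction of (non-DE) genes assigned to them, and
#'   the SD of the common per-sample module factor added to member genes.
#'   Planted DE genes stay outside modules so their residual SD is exactly
#'   sigma_g. Even without modules the planted DE genes form a shared
#'   high-variance co-expression block (their case/control shift covaries
#'   across samples), which is what the study-quality indices key on.
#' @param dropout_fraction Per-study fraction of genes removed at random to
#'   emulate platform differences (default 0: full shared universe).
#' @param corrupt_study Optional index of one study to regenerate with no
#'   shared structure (fresh baselines, fresh modules, no DE signal).
#' @param n_mirna,mirna_de_count Number of miRNAs and planted DE miRNAs.
#' @param mirna_fc_min Planted linear fold change (|log2 difference| =
#'   log2 of this value).
#' @param mirna_sd Within-group SD of the miRNA log2 values.
#' @param mirna_n_case,mirna_n_control miRNA study group sizes (19/13
#'   default, the peripheral-blood design the workflow emulates).
#' @param targets_per_mirna True targets planted per DE miRNA.
#' @param targets_from `"universe"` (default) or `"de_genes"` - pool the
#'   true target genes are drawn from.
#' @param source_retention Length-3 probabilities, each in (0, 1], that a
#'   true target pair is reported by each prediction source.
#' @param decoys_per_source False target pairs added per source.
#' @param n_genesets,geneset_size_range Random gene sets for enrichment
#'   and QC.
#' @param signal_set_size,signal_set_ratio The "signal" gene set: its size
#'   and the fraction of members drawn from planted DE genes.
#' @param n_ppi_edges Random scored gene-gene edges for the network stage.
#' @param seed Integer RNG seed; all outputs are deterministic given it.
#' @return Validated list of class `sim_params`.
#' @export
sim_params <- function(n_studies = 5L, genes = 2000L,
                       n_case = 8L, n_control = 8L,
                       de_fraction = 0.05,
                       effect_size_range = c(0.8, 1.2),
                       direction = c("down", "both"),
                       baseline_mean = 7, baseline_sd = 2,
                       study_batch_sd = 0.3,
                       gene_noise_sd_range = c(0.2, 0.6),
                       n_modules = 5L, module_fraction = 0,
                       module_strength = 0.7,
                       dropout_fraction = 0,
                       corrupt_study = NULL,
                       n_mirna = 200L, mirna_de_count = 10L,
                       mirna_fc_min = 4,
                       mirna_sd = 0.5,
                       mirna_n_case = 19L, mirna_n_control = 13L,
                       targets_per_mirna = 20L,
                       targets_from = c("universe", "de_genes"),
                       source_retention = c(mirdb = 0.9, targetscan = 0.9,
                                            microt = 0.9),
                       decoys_per_source = 50L,
                       n_genesets = 30L, geneset_size_range = c(20L, 80L),
                       signal_set_size = 50L, signal_set_ratio = 0.5,
                       n_ppi_edges = 4000L,
                       seed = 1L) {
  direction <- match.arg(direction)
  targets_from <- match.arg(targets_from)
  p <- list(n_studies = as.integer(n_studies), genes = as.integer(genes),
            n_case = as.integer(rep_len(n_case, n_studies)),
            n_control = as.integer(rep_len(n_control, n_studies)),
            de_fraction = de_fraction,
            effect_size_range = effect_size_range, direction = direction,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            study_batch_sd = study_batch_sd,
            gene_noise_sd_range = gene_noise_sd_range,
            n_modules = as.integer(n_modules),
            module_fraction = module_fraction,
            module_strength = module_strength,
            dropout_fraction = dropout_fraction,
            corrupt_study = if (is.null(corrupt_study)) NULL else as.integer(corrupt_study),
            n_mirna = as.integer(n_mirna),
            mirna_de_count = as.integer(mirna_de_count),
            mirna_fc_min = mirna_fc_min, mirna_sd = mirna_sd,
            mirna_n_case = as.integer(mirna_n_case),
            mirna_n_control = as.integer(mirna_n_control),
            targets_per_mirna = as.integer(targets_per_mirna),
            targets_from = targets_from,
            source_retention = source_retention,
            decoys_per_source = as.integer(decoys_per_source),
            n_genesets = as.integer(n_genesets),
            geneset_size_range = as.integer(geneset_size_range),
            signal_set_size = as.integer(signal_set_size),
            signal_set_ratio = signal_set_ratio,
            n_ppi_edges = as.integer(n_ppi_edges),
            seed = as.integer(seed))
  with(p, {
    stopifnot(n_studies >= 1, genes >= 1, all(n_case >= 2), all(n_control >= 2),
              de_fraction >= 0, de_fraction <= 1,
              effect_size_range[1] <= effect_size_range[2],
              gene_noise_sd_range[1] <= gene_noise_sd_range[2],
              gene_noise_sd_range[1] > 0,
              n_mirna >= 1, mirna_de_count >= 0, mirna_fc_min > 1,
              mirna_sd > 0, mirna_n_case >= 2, mirna_n_control >= 2,
              targets_per_mirna >= 1,
              length(source_retention) == 3,
              dropout_fraction >= 0, dropout_fraction < 1,
              module_fraction >= 0, module_fraction <= 1,
              signal_set_ratio >= 0, signal_set_ratio <= 1)
    if (any(source_retention <= 0) || any(source_retention > 1)) {
      stop("source_retention probabilities must be in (0, 1]")
    }
    if (mirna_de_count > n_mirna) stop("mirna_de_count exceeds n_mirna")
    if (de_fraction > 0 && round(de_fraction * genes) < 1) {
      stop("de_fraction * genes < 1: no DE gene can be planted")
    }
  })
  structure(p, class = "sim_params")
}

gene_ids_ <- function(G) sprintf("g%04d", seq_len(G))
mirna_ids_ <- function(M) sprintf("mir%03d", seq_len(M))

# Shared ground-truth scaffold: DE genes, effects, module memberships.
# Consumes a fixed amount of RNG state regardless of parameter values so
# that e.g. scaling the effect-size range leaves all noise draws intact.
sim_truth_scaffold_ <- function(params) {
  G <- params$genes
  genes <- gene_ids_(G)
  n_de <- round(params$de_fraction * G)
  de_genes <- sort(sample(genes, n_de))
  u <- stats::runif(G)
  delta <- params$effect_size_range[1] +
    u * diff(params$effect_size_range)
  sign_draw <- sample(c(-1, 1), G, replace = TRUE)
  s <- if (params$direction == "down") rep(-1, G) else sign_draw
  effect <- stats::setNames(rep(0, G), genes)
  effect[de_genes] <- (delta * s)[match(de_genes, genes)]
  mu <- stats::rnorm(G, params$baseline_mean, params$baseline_sd)
  sigma <- stats::runif(G, params$gene_noise_sd_range[1],
                        params$gene_noise_sd_range[2])
  # modules over non-DE genes only: planted genes keep residual SD sigma_g
  module <- rep(0L, G)
  pool <- setdiff(seq_len(G), match(de_genes, genes))
  n_mod_genes <- round(params$module_fraction * G)
  if (params$n_modules > 0 && n_mod_genes > 0 && length(pool) > 0) {
    chosen <- sample(pool, min(n_mod_genes, length(pool)))
    module[chosen] <- rep_len(seq_len(params$n_modules), length(chosen))
  }
  list(genes = genes, de_genes = de_genes, effect = effect,
       mu = stats::setNames(mu, genes), sigma = stats::setNames(sigma, genes),
       module = stats::setNames(module, genes))
}

sim_one_study_ <- function(params, scaffold, k) {
  G <- params$genes
  n1 <- params$n_case[k]; n2 <- params$n_control[k]
  n <- n1 + n2
  z <- c(rep(1, n1), rep(0, n2))
  a <- stats::rnorm(G, 0, params$study_batch_sd)
  X <- scaffold$mu + a + outer(scaffold$effect, z) +
    matrix(stats::rnorm(G * n, 0, scaffold$sigma), G, n)
  if (params$n_modules > 0 && any(scaffold$module > 0)) {
    f <- matrix(stats::rnorm(params$n_modules * n, 0, params$module_strength),
                params$n_modules, n)
    inmod <- scaffold$module > 0
    X[inmod, ] <- X[inmod, ] + f[scaffold$module[inmod], ]
  }
  rownames(X) <- scaffold$genes
  colnames(X) <- sprintf("s%d_%s%02d", k,
                         c(rep("case", n1), rep("ctrl", n2)),
                         c(seq_len(n1), seq_len(n2)))
  if (params$dropout_fraction > 0) {
    keep <- sort(sample(G, round((1 - params$dropout_fraction) * G)))
    X <- X[keep, , drop = FALSE]
  }
  expression_study(sprintf("study%d", k), X,
                   c(rep("case", n1), rep("control", n2)))
}

# Label-independent regeneration: fresh baselines, fresh noise scales,
# fresh modules, no DE signal. The strongest form of discordance, giving
# the QC stage an unambiguous target.
sim_corrupt_study_ <- function(params, scaffold, k) {
  G <- params$genes
  n1 <- params$n_case[k]; n2 <- params$n_control[k]
  n <- n1 + n2
  mu2 <- stats::rnorm(G, params$baseline_mean, params$baseline_sd)
  sigma2 <- stats::runif(G, params$gene_noise_sd_range[1],
                         params$gene_noise_sd_range[2])
  module2 <- sample(c(rep(0L, G - round(params$module_fraction * G)),
                      rep_len(seq_len(max(params$n_modules, 1L)),
                              round(params$module_fraction * G))))
  X <- mu2 + matrix(stats::rnorm(G * n, 0, sigma2), G, n)
  if (params$n_modules > 0 && any(module2 > 0)) {
    f <- matrix(stats::rnorm(params$n_modules * n, 0, params$module_strength),
                params$n_modules, n)
    inmod <- module2 > 0
    X[inmod, ] <- X[inmod, ] + f[module2[inmod], ]
  }
  rownames(X) <- scaffold$genes
  colnames(X) <- sprintf("s%d_%s%02d", k,
                         c(rep("case", n1), rep("ctrl", n2)),
                         c(seq_len(n1), seq_len(n2)))
  expression_study(sprintf("study%d", k), X,
                   c(rep("case", n1), rep("control", n2)))
}

#' Simulate K concordant expression studies with planted DE signal
#'
#' Expression follows x_gj = mu_g + a_gk + z_j * effect_g + module factor
#' + eps_gj with per-gene baseline mu_g, per-gene-per-study batch offset
#' a_gk, case indicator z_j, planted log2 effect (negative by default:
#' downregulation in cases), shared co-expression modules and gene-specific
#' noise SD sigma_g. If `corrupt_study` is set, that study is regenerated
#' with no shared structure after all regular draws, so the remaining
#' studies are bit-identical to the uncorrupted run under the same seed.
#'
#' @param params A [sim_params()].
#' @return List with `collection` (a [study_collection()]) and `truth`
#'   (de_genes, named effect vector, module assignment, corrupted_study).
#' @export
simulate_studies <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_studies < 2L) stop("need at least 2 studies for a collection")
  set.seed(params$seed)
  scaffold <- sim_truth_scaffold_(params)
  studies <- lapply(seq_len(params$n_studies), function(k) {
    sim_one_study_(params, scaffold, k)
  })
  if (!is.null(params$corrupt_study)) {
    k <- params$corrupt_study
    if (k < 1 || k > params$n_studies) stop("corrupt_study index out of range")
    studies[[k]] <- sim_corrupt_study_(params, scaffold, k)
  }
  truth <- list(de_genes = scaffold$de_genes,
                effect = scaffold$effect,
                module = scaffold$module,
                de_mirnas = character(0),
                true_targets = NULL,
                corrupted_study = if (is.null(params$corrupt_study)) NULL
                                  else sprintf("study%d", params$corrupt_study))
  list(collection = study_collection(studies), truth = truth)
}

#' Simulate a two-group miRNA study with planted fold changes
#'
#' Planted DE miRNAs carry a case-minus-control log2 difference of exactly
#' -log2(`mirna_fc_min`) (downregulation, `direction = "down"`) or a random
#' sign; all other miRNAs are centered at zero difference. Extends the
#' truth table with `de_mirnas` and, for each DE miRNA,
#' `targets_per_mirna` true target genes drawn from the configured pool.
#'
#' @param params A [sim_params()].
#' @param truth Optional truth list from [simulate_studies()]; supplies the
#'   gene universe and planted DE genes for target assignment.
#' @return List with `study` (an [expression_study()]) and the extended
#'   `truth` (adds `de_mirnas`, `mirna_effect`, `true_targets` data.frame).
#' @export
simulate_mirna_study <- function(params = sim_params(), truth = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (params$mirna_de_count > params$n_mirna) {
    stop("mirna_de_count exceeds n_mirna")
  }
  set.seed(params$seed + 104729L)
  M <- params$n_mirna
  mirnas <- mirna_ids_(M)
  n1 <- params$mirna_n_case; n2 <- params$mirna_n_control
  de <- if (params$mirna_de_count > 0) sort(sample(mirnas, params$mirna_de_count)) else character(0)
  dlog <- log2(params$mirna_fc_min)
  sgn <- if (params$direction == "down") rep(-1, M) else sample(c(-1, 1), M, replace = TRUE)
  effect <- stats::setNames(rep(0, M), mirnas)
  effect[de] <- (dlog * sgn)[match(de, mirnas)]
  mu <- stats::rnorm(M, params$baseline_mean, params$baseline_sd)
  z <- c(rep(1, n1), rep(0, n2))
  X <- mu + outer(effect, z) +
    matrix(stats::rnorm(M * (n1 + n2), 0, params$mirna_sd), M, n1 + n2)
  rownames(X) <- mirnas
  colnames(X) <- sprintf("mir_%s%02d", c(rep("case", n1), rep("ctrl", n2)),
                         c(seq_len(n1), seq_len(n2)))
  study <- expression_study("mirna_study", X,
                            c(rep("case", n1), rep("control", n2)))
  genes <- if (!is.null(truth)) names(truth$effect) else gene_ids_(params$genes)
  pool <- if (params$targets_from == "de_genes") {
    if (!is.null(truth)) truth$de_genes else
      stop("targets_from = 'de_genes' requires a truth table")
  } else genes
  pairs <- NULL
  if (length(de) && length(pool)) {
    pairs <- do.call(rbind, lapply(de, function(m) {
      tg <- sample(pool, min(params$targets_per_mirna, length(pool)))
      data.frame(mirna_id = m, gene_id = tg, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(truth)) truth <- list(de_genes = character(0),
                                    effect = stats::setNames(numeric(0), character(0)))
  truth$de_mirnas <- de
  truth$mirna_effect <- effect
  truth$true_targets <- pairs
  list(study = study, truth = truth)
}

#' Simulate three target-prediction sources from planted truth
#'
#' Each true (miRNA, gene) pair is reported by source s with probability
#' `source_retention[s]`, always with region 3UTR. Each source additionally
#' reports `decoys_per_source` decoy pairs (absent from the truth) with a
#' mixed region distribution, drawn independently per source.
#'
#' @param params A [sim_params()].
#' @param truth Truth list containing `true_targets`.
#' @return Target record data.frame (columns `source`, `mirna_id`,
#'   `gene_id`, `region`, `score`), suitable for [build_target_map()].
#' @export
simulate_target_sources <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(truth$true_targets)) stop("truth has no true_targets")
  if (any(params$source_retention <= 0)) {
    stop("source_retention probabilities must be > 0")
  }
  set.seed(params$seed + 15485863L)
  srcs <- names(params$source_retention)
  if (is.null(srcs)) srcs <- paste0("source", 1:3)
  tp <- truth$true_targets
  genes <- names(truth$effect)
  if (!length(genes)) genes <- gene_ids_(params$genes)
  mirnas <- mirna_ids_(params$n_mirna)
  truth_key <- paste(tp$mirna_id, tp$gene_id)
  recs <- lapply(seq_along(srcs), function(i) {
    keep <- stats::runif(nrow(tp)) <= params$source_retention[i]
    true_part <- if (any(keep)) {
      data.frame(source = srcs[i], mirna_id = tp$mirna_id[keep],
                 gene_id = tp$gene_id[keep], region = "3UTR",
                 score = round(stats::runif(sum(keep), 0.5, 1), 4),
                 stringsAsFactors = FALSE)
    }
    nd <- params$decoys_per_source
    decoy_part <- NULL
    if (nd > 0) {
      dm <- sample(mirnas, nd, replace = TRUE)
      dg <- sample(genes, nd, replace = TRUE)
      ok <- !(paste(dm, dg) %in% truth_key)
      decoy_part <- data.frame(source = srcs[i], mirna_id = dm[ok],
                               gene_id = dg[ok],
                               region = sample(REGION_LEVELS, sum(ok),
                                               replace = TRUE,
                                               prob = c(0.5, 0.3, 0.2)),
                               score = round(stats::runif(sum(ok), 0.1, 1), 4),
                               stringsAsFactors = FALSE)
    }
    rbind(true_part, decoy_part)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate a gene-set collection with one planted signal set
#'
#' Emits a "signal" set whose members are drawn from the planted DE genes
#' at ratio `signal_set_ratio`, one set per co-expression module (so the
#' external QC index has pathway knowledge matching the coexpression
#' structure), and `n_genesets` random sets.
#'
#' @param params A [sim_params()].
#' @param truth Truth list from [simulate_studies()].
#' @return A [gene_set_collection()] over the simulated universe.
#' @export
simulate_genesets <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 32452843L)
  genes <- names(truth$effect)
  if (!length(genes)) genes <- gene_ids_(params$genes)
  G <- length(genes)
  if (params$signal_set_size > G ||
      params$geneset_size_range[2] > G) {
    stop("gene-set size exceeds universe size")
  }
  sets <- list(); desc <- character(0)
  n_sig <- min(round(params$signal_set_ratio * params$signal_set_size),
               length(truth$de_genes))
  sig <- c(sample(truth$de_genes, n_sig),
           sample(setdiff(genes, truth$de_genes),
                  params$signal_set_size - n_sig))
  sets[["signal_set"]] <- sort(sig)
  desc["signal_set"] <- "planted DE signal set"
  if (!is.null(truth$module)) {
    for (m in sort(unique(truth$module[truth$module > 0]))) {
      nm <- sprintf("module_%02d", m)
      sets[[nm]] <- sort(names(truth$module)[truth$module == m])
      desc[nm] <- "co-expression module"
    }
  }
  sizes <- sample(seq(params$geneset_size_range[1],
                      params$geneset_size_range[2]),
                  params$n_genesets, replace = TRUE)
  for (i in seq_len(params$n_genesets)) {
    nm <- sprintf("random_%03d", i)
    sets[[nm]] <- sort(sample(genes, sizes[i]))
    desc[nm] <- "random set"
  }
  gene_set_collection(sets, genes, desc)
}

sim_ppi_ <- function(params, truth) {
  set.seed(params$seed + 49979687L)
  genes <- names(truth$effect)
  n <- params$n_ppi_edges
  # half the edges within co-expression modules (plausible functional
  # coupling), half uniform
  n_mod <- if (any(truth$module > 0)) round(n / 2) else 0L
  ab <- NULL
  if (n_mod > 0) {
    mods <- sample(unique(truth$module[truth$module > 0]), n_mod, replace = TRUE)
    ab <- t(vapply(mods, function(m) {
      sample(names(truth$module)[truth$module == m], 2L)
    }, character(2)))
  }
  a2 <- matrix(sample(genes, 2 * (n - n_mod), replace = TRUE), ncol = 2)
  a2 <- a2[a2[, 1] != a2[, 2], , drop = FALSE]
  ab <- rbind(ab, a2)
  df <- data.frame(gene_a = pmin(ab[, 1], ab[, 2]),
                   gene_b = pmax(ab[, 1], ab[, 2]),
                   combined_score = round(stats::runif(nrow(ab), 0.15, 0.999), 3),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, -df$combined_score), ]
  df <- df[!duplicated(df[c("gene_a", "gene_b")]), ]
  rownames(df) <- NULL
  df
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Generates every input the pipeline consumes (K expression studies with
#' annotation, a miRNA study, a GMT gene-set collection, a scored PPI edge
#' list, three target source TSVs) plus the published reference fixtures
#' (see [published_mirna_table()] and [published_target_fixture()]), and a
#' JSON manifest recording files, seed and ground truth.
#'
#' @param params A [sim_params()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_bundle <- function(params = sim_params(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_studies(params)
  msim <- simulate_mirna_study(params, sim$truth)
  truth <- msim$truth
  targets <- simulate_target_sources(params, truth)
  gs <- simulate_genesets(params, truth)
  ppi <- sim_ppi_(params, truth)

  files <- list()
  ann_all <- NULL
  for (s in sim$collection$studies) {
    mp <- file.path(dir, sprintf("expr_%s.tsv", s$study_id))
    ap <- file.path(dir, sprintf("ann_%s.tsv", s$study_id))
    write_expression(s, mp, ap)
    files$expression[[s$study_id]] <- mp
    files$annotation[[s$study_id]] <- ap
  }
  mp <- file.path(dir, "expr_mirna.tsv")
  ap <- file.path(dir, "ann_mirna.tsv")
  write_expression(msim$study, mp, ap)
  files$mirna_expression <- mp
  files$mirna_annotation <- ap
  gp <- file.path(dir, "genesets.gmt")
  write_genesets(gs, gp)
  files$genesets <- gp
  pp <- file.path(dir, "ppi.tsv")
  write_tsv_(ppi, pp)
  files$ppi <- pp
  files$targets <- as.list(write_targets(targets, dir))
  # published structural fixtures (printed miRNA table and pairing edges)
  pub <- published_mirna_table()
  pubp <- file.path(dir, "published_mirna_de.tsv")
  write_tsv_(pub, pubp)
  files$published_mirna_de <- pubp
  pubt <- published_target_fixture(include_kif3a = FALSE)
  files$published_targets <- as.list(write_targets(pubt, dir, prefix = "published_targets"))
  manifest <- list(seed = params$seed, files = files,
                   truth = list(de_genes = truth$de_genes,
                                de_mirnas = truth$de_mirnas,
                                corrupted_study = truth$corrupted_study))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
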