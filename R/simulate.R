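# Synthetic multi-cohort expression studies with planted coexpression
# modules, hub driver genes and signature-responsive conditions. The
# generator is the benchmark substrate for every downstream stage: its
# ground truth (module assignments, drivers, planted signature directions)
# is machine-readable so recovery can be scored exactly.

#' Define a synthetic multi-cohort study
#'
#' Each module is generated from a latent factor per cohort: the module's
#' driver gene equals the factor plus a small noise term, and every other
#' member loads on the driver (`member = beta * driver + noise`). The member
#' noise standard deviation is `noise_sd * beta * sqrt((1 - rho) / rho)`, so
#' that at `noise_sd = 1` the expected within-module correlation is
#' approximately `rho`, and correlations approach 1 as `noise_sd` approaches
#' 0. Background genes are independent noise. Every gene receives a baseline
#' (shared across cohorts) and a per-cohort additive batch shift. All values
#' are on log2 scale by convention.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort samples per cohort (scalar or one per cohort).
#' @param modules list of module descriptors, each
#'   `list(module_id =, n_members =, rho =)` with `rho` in `[0, 1)`.
#' @param n_background_genes independent noise genes.
#' @param driver_per_module hub drivers per module (>= 1).
#' @param driver_loading loading `beta` in `(0, 1]` of members on the driver.
#' @param noise_sd member/background noise scale (> 0).
#' @param batch_shift_sd sd of the per-cohort, per-gene additive shift (>= 0).
#' @param signature_effect default log2 effect used when planting signature
#'   responses downstream.
#' @param seed integer seed; identical spec + seed reproduces byte-identical
#'   output (R's Mersenne-Twister RNG).
#' @return an object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_cohorts = 3,
                                 samples_per_cohort = 50,
                                 modules = list(
                                   list(module_id = "M1", n_members = 10, rho = 0.6),
                                   list(module_id = "M2", n_members = 15, rho = 0.6),
                                   list(module_id = "M3", n_members = 20, rho = 0.6)
                                 ),
                                 n_background_genes = 60,
                                 driver_per_module = 1,
                                 driver_loading = 0.9,
                                 noise_sd = 1,
                                 batch_shift_sd = 0.3,
                                 signature_effect = 2,
                                 seed = 1) {
  stopifnot(
    n_cohorts >= 1, all(samples_per_cohort >= 1),
    n_background_genes >= 0, driver_per_module >= 1,
    driver_loading > 0, driver_loading <= 1,
    noise_sd > 0, batch_shift_sd >= 0
  )
  if (length(samples_per_cohort) == 1) {
    samples_per_cohort <- rep(samples_per_cohort, n_cohorts)
  }
  if (length(samples_per_cohort) != n_cohorts) {
    stop("samples_per_cohort must be scalar or length n_cohorts")
  }
  for (m in modules) {
    if (!all(c("module_id", "n_members", "rho") %in% names(m))) {
      stop("each module needs module_id, n_members, rho")
    }
    if (m$rho < 0 || m$rho >= 1) stop("rho must be in [0, 1)")
    if (m$n_members < driver_per_module + 1) {
      stop("module ", m$module_id, " too small for its drivers")
    }
  }
  if (anyDuplicated(vapply(modules, `[[`, "", "module_id"))) {
    stop("duplicate module ids")
  }
  structure(
    list(
      n_cohorts = as.integer(n_cohorts),
      samples_per_cohort = as.integer(samples_per_cohort),
      modules = modules,
      n_background_genes = as.integer(n_background_genes),
      driver_per_module = as.integer(driver_per_module),
      driver_loading = driver_loading,
      noise_sd = noise_sd,
      batch_shift_sd = batch_shift_sd,
      signature_effect = signature_effect,
      seed = as.integer(seed)
    ),
    class = "synthetic_study_spec"
  )
}

#' Gene ids for a study spec
#' @noRd
spec_gene_ids <- function(spec) {
  ids <- character(0)
  for (m in spec$modules) {
    idx <- seq_len(m$n_members)
    nm <- ifelse(
      idx <= spec$driver_per_module,
      sprintf("%s_DRV%d", m$module_id, idx),
      sprintf("%s_mem%02d", m$module_id, idx)
    )
    ids <- c(ids, nm)
  }
  c(ids, sprintf("BG_%03d", seq_len(spec$n_background_genes)))
}

#' Generate a multi-cohort synthetic study
#'
#' @param spec a [synthetic_study_spec()].
#' @return a list with `cohorts` (named list of genes-by-samples log2
#'   matrices sharing the same gene ids) and `truth` (module assignment per
#'   gene, driver genes per module, and an initially empty
#'   `signature_direction` record filled by [plant_signature_response()]
#'   callers).
#' @export
generate_multi_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_study_spec")) stop("spec must be a synthetic_study_spec")
  genes <- spec_gene_ids(spec)
  n_genes <- length(genes)

  # gene baselines are drawn from the spec seed itself, before any cohort
  # sub-stream, so they are shared across cohorts
  set.seed(spec$seed)
  baseline <- rnorm(n_genes, mean = 8, sd = 1.5)
  names(baseline) <- genes

  cohorts <- vector("list", spec$n_cohorts)
  names(cohorts) <- sprintf("cohort_%d", seq_len(spec$n_cohorts))
  for (ci in seq_len(spec$n_cohorts)) {
    # fixed per-cohort sub-stream: adding a cohort never perturbs earlier ones
    set.seed((spec$seed + 77003L * ci) %% 2147483647L)
    s <- spec$samples_per_cohort[ci]
    mat <- matrix(NA_real_, nrow = n_genes, ncol = s,
                  dimnames = list(genes, sprintf("%s_S%03d", names(cohorts)[ci], seq_len(s))))
    row <- 1L
    for (m in spec$modules) {
      factor_m <- rnorm(s)
      drivers <- matrix(rnorm(s * spec$driver_per_module, sd = 0.1 * spec$noise_sd),
                        nrow = spec$driver_per_module)
      drivers <- sweep(drivers, 2, factor_m, "+")
      lead <- drivers[1, ]
      for (j in seq_len(m$n_members)) {
        if (j <= spec$driver_per_module) {
          mat[row, ] <- drivers[j, ]
        } else if (m$rho == 0) {
          mat[row, ] <- rnorm(s, sd = spec$noise_sd)
        } else {
          msd <- spec$noise_sd * spec$driver_loading * sqrt((1 - m$rho) / m$rho)
          mat[row, ] <- spec$driver_loading * lead + rnorm(s, sd = msd)
        }
        row <- row + 1L
      }
    }
    if (spec$n_background_genes > 0) {
      bg <- matrix(rnorm(spec$n_background_genes * s, sd = spec$noise_sd),
                   nrow = spec$n_background_genes)
      mat[row:(row + spec$n_background_genes - 1L), ] <- bg
    }
    batch <- rnorm(n_genes, sd = spec$batch_shift_sd)
    mat <- mat + baseline + batch
    cohorts[[ci]] <- mat
  }

  assignment <- rep("background", n_genes)
  names(assignment) <- genes
  driver_genes <- list()
  for (m in spec$modules) {
    members <- genes[startsWith(genes, paste0(m$module_id, "_"))]
    assignment[members] <- m$module_id
    driver_genes[[m$module_id]] <- members[seq_len(spec$driver_per_module)]
  }
  truth <- list(
    module_assignment = assignment,
    driver_genes = driver_genes,
    signature_direction = list()
  )
  list(cohorts = cohorts, truth = truth)
}

#' Plant a prognostic-signature response into selected samples
#'
#' Adds `+delta` to the poor-prognosis genes and `-delta` to the
#' good-prognosis genes in samples labelled as injured; all other entries
#' are untouched. Modeling a reversal (e.g., a knockout that restores the
#' good-prognosis state) is done by a second call with negated `delta`.
#'
#' @param mat genes-by-samples log2 matrix.
#' @param signature a [signature_definition()].
#' @param condition_labels one label per sample; each must be
#'   `injured_label` or `reference_label`.
#' @param delta log2 effect size (may be negative).
#' @param injured_label,reference_label the two admissible labels.
#' @return the modified matrix.
#' @export
plant_signature_response <- function(mat, signature, condition_labels, delta,
                                     injured_label = "injured",
                                     reference_label = "reference") {
  validate_expression_matrix(mat)
  if (length(condition_labels) != ncol(mat)) {
    stop("condition_labels must cover all samples")
  }
  bad <- setdiff(unique(condition_labels), c(injured_label, reference_label))
  if (length(bad)) stop("unknown condition label: ", paste(bad, collapse = ", "))
  missing_genes <- setdiff(c(signature$poor_genes, signature$good_genes), rownames(mat))
  if (length(missing_genes)) {
    stop("signature gene absent from matrix: ", paste(missing_genes, collapse = ", "))
  }
  inj <- condition_labels == injured_label
  mat[signature$poor_genes, inj] <- mat[signature$poor_genes, inj] + delta
  mat[signature$good_genes, inj] <- mat[signature$good_genes, inj] - delta
  mat
}

#' Write synthetic fixtures to disk
#'
#' Writes one TSV per cohort, a JSON ground-truth file and, when a signature
#' is supplied, a two-set GMT. Returns a manifest of paths and md5 checksums.
#'
#' @param cohorts named list of expression matrices.
#' @param truth ground-truth list as returned by [generate_multi_cohort()].
#' @param dir output directory (created if needed).
#' @param signature optional [signature_definition()] written as GMT.
#' @return data.frame with columns `file` and `md5`.
#' @export
write_fixtures <- function(cohorts, truth, dir, signature = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(cohorts)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_expression_tsv(cohorts[[nm]], p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, tp)
  if (!is.null(signature)) {
    gp <- file.path(dir, "signature.gmt")
    write_gmt(list(
      list(name = paste0(signature$name, "_POOR"),
           description = "poor-prognosis subset", genes = signature$poor_genes),
      list(name = paste0(signature$name, "_GOOD"),
           description = "good-prognosis subset", genes = signature$good_genes)
    ), gp)
    paths <- c(paths, gp)
  }
  data.frame(file = paths, md5 = file_checksums(paths), stringsAsFactors = FALSE)
}
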