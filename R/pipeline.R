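# End-to-end orchestration: simulate (or read) cohorts, meta-analyse edges,
# build the planar network, detect modules, rank key drivers, annotate
# modules, call the signature status, and shortlist candidates. Every run
# writes per-stage outputs plus a JSON manifest (config, seeds, paths,
# checksums) from which the run is fully regenerable.

#' Pipeline configuration with stage defaults
#'
#' @param n_perm permutations per gene pair and cohort.
#' @param n_resample resampling iterations for the ICS null (10,000 by
#'   default).
#' @param edge_fdr FDR threshold for significant edges (0.05).
#' @param top_var gene-subset size by variance when no subset is given.
#' @param scales community-detection resolutions.
#' @param module_scale scale whose modules feed key-driver analysis.
#' @param min_size minimum module size.
#' @param n_max maximum key-driver neighborhood depth.
#' @param weight_exponent GSEA weighting exponent.
#' @param gsea_n_perm GSEA permutations.
#' @param status_fdr signature-status FDR cutoff.
#' @param shortlist_require annotation flags required of shortlisted
#'   candidates.
#' @param top_drivers_per_module drivers per module entering the shortlist.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_perm = 200, n_resample = 10000, edge_fdr = 0.05,
                            top_var = 500, scales = c(0.5, 1, 2),
                            module_scale = 1, min_size = 5, n_max = 5,
                            weight_exponent = 1, gsea_n_perm = 1000,
                            status_fdr = 0.25,
                            shortlist_require = c("liver_expression_high",
                                                  "liver_disease_association",
                                                  "druggable"),
                            top_drivers_per_module = 2, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Shortlist key drivers by annotation flags
#'
#' Keeps drivers whose annotation satisfies every required flag; an unknown
#' (NA) value fails a required flag, since absence of evidence is not
#' negative evidence but cannot support a shortlist either. Driver ranking
#' order is preserved. Genes without any annotation row are returned in a
#' separate `unannotated` table rather than silently dropped.
#'
#' @param drivers data.frame from [key_driver_analysis()] (needs `gene`).
#' @param annotations data.frame from [read_annotations_tsv()].
#' @param require character subset of the three flag names; empty = no
#'   filtering.
#' @return list with `shortlist` and `unannotated` data.frames.
#' @export
filter_candidates <- function(drivers, annotations,
                              require = c("liver_expression_high",
                                          "liver_disease_association",
                                          "druggable")) {
  flags <- c("liver_expression_high", "liver_disease_association", "druggable")
  if (!all(require %in% flags)) stop("unknown flag in require")
  idx <- match(drivers$gene, annotations$gene)
  annotated <- !is.na(idx)
  keep <- annotated
  for (fl in require) {
    val <- annotations[[fl]][idx]
    keep <- keep & !is.na(val) & val
  }
  shortlist <- drivers[keep, , drop = FALSE]
  if (length(require) == 0) shortlist <- drivers[annotated, , drop = FALSE]
  unannot <- drivers[!annotated, , drop = FALSE]
  rownames(shortlist) <- rownames(unannot) <- NULL
  list(shortlist = shortlist, unannotated = unannot)
}

#' Tumor volume from caliper measurements
#'
#' `0.5 * length * width^2`, the standard ellipsoid approximation for
#' subcutaneous xenograft measurements (mm input, mm^3 output).
#'
#' @param length,width positive measurements in mm (vectorized).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) stop("length and width must be positive")
  0.5 * length * width^2
}

#' Ground-truth annotation table for a synthetic study
#'
#' Planted drivers get all three flags true (so the benchmark shortlist can
#' recover them); other module members get liver flags true but druggable
#' false; background genes are unknown throughout.
#' @noRd
synthetic_annotations <- function(truth) {
  genes <- names(truth$module_assignment)
  drivers <- unlist(truth$driver_genes, use.names = FALSE)
  in_module <- truth$module_assignment != "background"
  data.frame(
    gene = genes,
    liver_expression_high = ifelse(in_module, TRUE, NA),
    liver_disease_association = ifelse(in_module, TRUE, NA),
    druggable = ifelse(genes %in% drivers, TRUE, ifelse(in_module, FALSE, NA)),
    evidence_note = ifelse(genes %in% drivers, "planted driver", ""),
    stringsAsFactors = FALSE
  )
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> edge meta-analysis -> PMFG -> multiscale
#' modules -> key drivers -> annotation -> signature status -> candidate
#' shortlist, writing each stage's output and a manifest under `out_dir`.
#' With a `spec`, cohorts are simulated and a signature response (effect
#' `spec$signature_effect` on dedicated background genes) is planted into
#' an injured/reference split of extra samples; with `input_paths`, cohorts
#' (TSV/GCT), an optional signature GMT, annotation TSV and gene-set GMT
#' are read from disk.
#'
#' @param config a [pipeline_config()].
#' @param spec optional [synthetic_study_spec()].
#' @param input_paths optional list with `cohorts` (character paths),
#'   optional `signature`, `annotations`, `collections`, `test`, `reference`.
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, spec = NULL, input_paths = NULL,
                         out_dir = tempfile("hepnet_run_")) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  if (is.null(spec) == is.null(input_paths)) {
    stop("provide exactly one of spec or input_paths")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_log <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_log[[name]] <<- "ok"
    res
  }
  outputs <- character(0)
  emit <- function(rel, writer) {
    p <- file.path(out_dir, rel)
    writer(p)
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs ---
  truth <- NULL
  signature <- NULL
  annotations <- NULL
  collections <- NULL
  test_mat <- ref_mat <- NULL
  if (!is.null(spec)) {
    sim <- run_stage("simulate", function() generate_multi_cohort(spec))
    cohorts <- sim$cohorts
    truth <- sim$truth
    # signature genes live among the background so the network stages stay
    # uncontaminated; requires enough background genes
    n_bg <- spec$n_background_genes
    n_sig <- min(20L, max(2L, n_bg %/% 3L))
    if (n_bg >= 2 * n_sig) {
      bg <- sprintf("BG_%03d", seq_len(n_bg))
      signature <- signature_definition("synthetic_pls",
                                        poor_genes = bg[seq_len(n_sig)],
                                        good_genes = bg[n_sig + seq_len(n_sig)])
      set.seed((spec$seed + 5557L) %% 2147483647L)
      n_each <- 20L
      genes <- rownames(cohorts[[1]])
      pair <- matrix(rnorm(length(genes) * 2 * n_each, sd = spec$noise_sd),
                     nrow = length(genes),
                     dimnames = list(genes, c(sprintf("inj_%02d", seq_len(n_each)),
                                              sprintf("ref_%02d", seq_len(n_each)))))
      labels <- rep(c("injured", "reference"), each = n_each)
      pair <- plant_signature_response(pair, signature, labels,
                                       delta = spec$signature_effect)
      test_mat <- pair[, labels == "injured", drop = FALSE]
      ref_mat <- pair[, labels == "reference", drop = FALSE]
      truth$signature_direction <- list(injured = list(poor = "induced",
                                                       good = "suppressed"))
    }
    annotations <- synthetic_annotations(truth)
    # annotate against the planted module memberships as reference sets
    collections <- lapply(names(truth$driver_genes), function(mid) {
      list(name = paste0("PLANTED_", mid), description = "planted module",
           genes = names(truth$module_assignment)[truth$module_assignment == mid])
    })
    names(collections) <- vapply(collections, `[[`, "", "name")
    for (nm in names(cohorts)) {
      local({
        m <- cohorts[[nm]]
        emit(paste0(nm, ".tsv"), function(p) write_expression_tsv(m, p))
      })
    }
    emit("ground_truth.json", function(p) {
      jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  } else {
    cohorts <- run_stage("load", function() {
      ms <- lapply(input_paths$cohorts, function(p) {
        if (grepl("\\.gct$", p, ignore.case = TRUE)) read_gct(p) else read_expression_tsv(p)
      })
      names(ms) <- sub("\\.(tsv|gct)$", "", basename(input_paths$cohorts),
                       ignore.case = TRUE)
      ms
    })
    if (!is.null(input_paths$signature)) signature <- read_signature_gmt(input_paths$signature)
    if (!is.null(input_paths$annotations)) annotations <- read_annotations_tsv(input_paths$annotations)
    if (!is.null(input_paths$collections)) collections <- read_gmt(input_paths$collections)
    if (!is.null(input_paths$test)) test_mat <- read_expression_tsv(input_paths$test)
    if (!is.null(input_paths$reference)) ref_mat <- read_expression_tsv(input_paths$reference)
  }

  # --- meta-analysis ---
  edges_all <- run_stage("meta", function() {
    edge_meta_analysis(cohorts, n_perm = config$n_perm,
                       n_resample = config$n_resample, seed = config$seed,
                       top_var = config$top_var)
  })
  emit("edge_stats.tsv", function(p) {
    write.table(edges_all, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  edges_sig <- significant_edges(edges_all, q_threshold = config$edge_fdr)
  emit("edges_significant.tsv", function(p) {
    write.table(edges_sig, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- planar network and modules ---
  network <- run_stage("network", function() build_pmfg(edges_sig))
  emit("network.json", function(p) {
    jsonlite::write_json(
      list(nodes = network$nodes, edges = network$edges, log = network$log),
      p, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  })
  modules <- run_stage("modules", function() {
    detect_modules_multiscale(network, scales = config$scales,
                              min_size = config$min_size, seed = config$seed)
  })
  emit("modules.tsv", function(p) {
    write.table(modules, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- key drivers ---
  mods_at_scale <- modules[modules$scale == config$module_scale, , drop = FALSE]
  drivers <- run_stage("kda", function() {
    if (nrow(mods_at_scale) == 0) {
      return(data.frame(gene = character(0), module_id = character(0),
                        optimal_n = integer(0), neighborhood_size = integer(0),
                        overlap = integer(0), fold_enrichment = numeric(0),
                        p = numeric(0), q = numeric(0), rank = integer(0)))
    }
    key_driver_analysis_all(network, mods_at_scale, n_max = config$n_max)
  })
  emit("key_drivers.tsv", function(p) {
    write.table(drivers, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- module annotation ---
  if (!is.null(collections) && length(collections) > 0 && nrow(mods_at_scale) > 0) {
    ann <- run_stage("annotate", function() {
      universe <- Reduce(intersect, lapply(cohorts, rownames))
      annotate_modules(mods_at_scale, collections, universe)
    })
    emit("module_annotation.tsv", function(p) {
      write.table(ann, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  # --- signature status ---
  status <- NULL
  if (!is.null(signature) && !is.null(test_mat) && !is.null(ref_mat)) {
    status <- run_stage("signature_status", function() {
      signature_status(test_mat, ref_mat, signature,
                       n_perm = config$gsea_n_perm, seed = config$seed,
                       fdr_cut = config$status_fdr,
                       weight_exponent = config$weight_exponent)
    })
    emit("signature_status.json", function(p) {
      jsonlite::write_json(
        list(poor = status$poor, good = status$good, call = status$call,
             conflict = status$conflict),
        p, auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
    })
  }

  # --- candidate shortlist ---
  shortlist <- NULL
  if (!is.null(annotations) && nrow(drivers) > 0) {
    shortlist <- run_stage("shortlist", function() {
      top <- do.call(rbind, lapply(split(drivers, drivers$module_id), function(d) {
        head(d[order(d$rank), , drop = FALSE], config$top_drivers_per_module)
      }))
      filter_candidates(top, annotations, require = config$shortlist_require)
    })
    emit("shortlist.tsv", function(p) {
      write.table(shortlist$shortlist, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    emit("shortlist_unannotated.tsv", function(p) {
      write.table(shortlist$unannotated, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hepnet")),
    config = unclass(config),
    spec = if (!is.null(spec)) unclass(spec) else NULL,
    input_paths = input_paths,
    stages = stage_log,
    signature_call = if (!is.null(status)) status$call else NULL,
    files = data.frame(
      file = basename(outputs),
      md5 = file_checksums(outputs),
      stringsAsFactors = FALSE
    )
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
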