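#' Gradient components of one connectome
#'
#' Convenience chain for a single connectivity matrix: row sparsification,
#' cosine affinity, diffusion-map embedding.
#'
#' @param m \code{connectivity_matrix} (or square matrix).
#' @param keep_fraction row-wise fraction of entries kept (default 0.10).
#' @param alpha anisotropic diffusion normalization (default 0.5).
#' @param diffusion_time diffusion time (0 = multiscale, the default).
#' @param n_components components retained (default 10).
#' @return a \code{gradient_set}.
#' @export
connectome_gradients <- function(m, keep_fraction = 0.10, alpha = 0.5,
                                 diffusion_time = 0, n_components = 10L) {
  diffusion_map(cosine_affinity(sparsify_rows(m, keep_fraction)),
                alpha = alpha, diffusion_time = diffusion_time,
                n_components = n_components)
}

#' Group-template gradients from a mean connectome
#'
#' Embeds the element-wise mean of a group's connectomes (typically the
#' control group) and fixes component signs so the principal gradient runs
#' from the designated primary network (low) to the designated association
#' network (high).
#'
#' @param mats list of \code{connectivity_matrix} objects.
#' @param partition ROI-to-network partition (see [network_scores()]).
#' @param assoc_network,primary_network network labels anchoring the sign
#'   convention (defaults DMN and VIS).
#' @param ... passed to [connectome_gradients()].
#' @return an oriented \code{gradient_set} template.
#' @export
group_template <- function(mats, partition, assoc_network = "DMN",
                           primary_network = "VIS", ...) {
  mean_mat <- Reduce(`+`, lapply(mats, function(m) unclass(as.matrix(m)))) /
    length(mats)
  dimnames(mean_mat) <- dimnames(as.matrix(mats[[1L]]))
  gs <- connectome_gradients(mean_mat, ...)
  part <- as_partition(partition)
  rois <- rownames(gs$scores)
  orient_gradients(gs,
                   assoc_rois = rois[part[rois] == assoc_network],
                   primary_rois = rois[part[rois] == primary_network])
}

#' Align subject gradient sets to a group template
#'
#' Runs iterative Procrustes alignment with the template as the first
#' (reference-initializing) set and returns the aligned subject sets.
#'
#' @param sets named list of subject \code{gradient_set}s.
#' @param template template \code{gradient_set} (see [group_template()]).
#' @param n_iter Procrustes iterations (default 10).
#' @return named list of aligned subject \code{gradient_set}s (the
#'   alignment result is attached as attribute \code{"alignment"}).
#' @export
align_to_template <- function(sets, template, n_iter = 10L) {
  res <- procrustes_align(c(list(template), unname(sets)), n_iter = n_iter)
  aligned <- res$aligned[-1L]
  names(aligned) <- names(sets)
  attr(aligned, "alignment") <- res[c("rotations", "reference",
                                      "iterations_run", "discrepancy")]
  aligned
}

#' Default pipeline configuration
#'
#' @param out_dir output directory for artifacts.
#' @param cohort list of [cohort_config()] arguments (simulation mode), or
#'   \code{NULL} when \code{inputs} point at existing files.
#' @param inputs list with \code{dir} (a cohort directory in the
#'   [write_cohort()] layout); ignored in simulation mode.
#' @param keep_fraction,alpha,diffusion_time,n_components embedding
#'   parameters.
#' @param n_grid,density_floor vertex-area density parameters.
#' @param q FDR level; \code{folds} SVM cross-validation folds.
#' @param assoc_network,primary_network sign-convention anchors.
#' @param regress_structural also covariate-regress structural connectomes
#'   (default FALSE: only functional edges are residualized).
#' @param seed seed funnelled into every stochastic stage.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, cohort = list(), inputs = NULL,
                            keep_fraction = 0.10, alpha = 0.5,
                            diffusion_time = 0, n_components = 10L,
                            n_grid = 256L, density_floor = 1e-12,
                            q = 0.05, folds = 5L,
                            assoc_network = "DMN", primary_network = "VIS",
                            regress_structural = FALSE, seed = 1L) {
  list(out_dir = out_dir, cohort = cohort, inputs = inputs,
       keep_fraction = keep_fraction, alpha = alpha,
       diffusion_time = diffusion_time, n_components = as.integer(n_components),
       n_grid = as.integer(n_grid), density_floor = density_floor,
       q = q, folds = as.integer(folds),
       assoc_network = assoc_network, primary_network = primary_network,
       regress_structural = regress_structural, seed = as.integer(seed))
}

#' Run the full gradient analysis pipeline
#'
#' Orchestrates, in order: cohort simulation (or ingest of an existing
#' cohort directory), functional and structural connectome construction
#' with covariate regression, diffusion-map embedding, Procrustes
#' alignment to the control template, gradient-span and ROI/network group
#' statistics with FDR, SVM classification of network gradient features,
#' and covariate-controlled correlation of gradient change with clinical
#' change. Every artifact is written under \code{config$out_dir} and
#' listed in a checksummed manifest; with a fixed seed the manifest
#' checksums of deterministic stages are bit-stable across reruns.
#'
#' @param config list from [pipeline_config()], or the path of a YAML file
#'   holding those fields.
#' @return (invisibly) list with the manifest data.frame and the in-memory
#'   results of each stage (templates, aligned gradients, spans, stats,
#'   classifier reports, correlations, truth when simulated).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(pipeline_config, config[setdiff(names(config), character(0))])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  log_msg <- function(...) message("[connectograd] ", ...)
  add_artifact <- local({
    function(path, format, stage) {
      manifest[[length(manifest) + 1L]] <<- data.frame(
        path = path, format = format, stage = stage,
        checksum = unname(tools::md5sum(path)),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        stringsAsFactors = FALSE)
    }
  })
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- stage: ingest / simulate -------------------------------------------
  truth <- NULL
  if (length(cfg$cohort) || is.null(cfg$inputs)) {
    run_stage("simulate", {
      log_msg("simulating cohort")
      cc_args <- cfg$cohort
      if (is.null(cc_args$seed)) cc_args$seed <- cfg$seed
      cohort <- generate_cohort(do.call(cohort_config, cc_args))
      cohort_dir <- file.path(cfg$out_dir, "cohort")
      write_cohort(cohort, cohort_dir)
      add_artifact(file.path(cohort_dir, "subjects.tsv"), "tsv", "simulate")
      add_artifact(file.path(cohort_dir, "partition.tsv"), "tsv", "simulate")
      add_artifact(file.path(cohort_dir, "truth.json"), "json", "simulate")
      data <- read_cohort(cohort_dir)
      truth <- data$truth
      data
    }) -> data
  } else {
    run_stage("ingest", {
      dir <- cfg$inputs$dir
      need <- c(file.path(dir, "subjects.tsv"), file.path(dir, "partition.tsv"),
                file.path(dir, "timeseries"), file.path(dir, "areas"))
      missing <- need[!file.exists(need)]
      if (length(missing)) {
        stop("missing input path(s): ", paste(missing, collapse = ", "))
      }
      log_msg("reading cohort from ", dir)
      data <- read_cohort(dir)
      truth <- data$truth
      data
    }) -> data
  }

  subjects <- data$subjects
  partition <- data$partition
  keys <- names(data$timeseries)
  key_subject <- sub("_(control|pre|post)$", "", keys)
  key_session <- sub("^.*_", "", keys)
  controls <- subjects$subject_id[subjects$group == "control"]
  patients <- subjects$subject_id[subjects$group == "patient"]

  # ---- stage: connectomes --------------------------------------------------
  run_stage("connectomes", {
    log_msg("building connectomes for ", length(keys), " sessions")
    fc <- lapply(data$timeseries, functional_connectome)
    covs <- subjects[match(key_subject, subjects$subject_id),
                     c("age", "sex"), drop = FALSE]
    fc <- regress_confounds(fc, covs)
    names(fc) <- keys
    kl <- lapply(data$vertex_areas, structural_connectome,
                 n_points = cfg$n_grid, floor = cfg$density_floor)
    if (isTRUE(cfg$regress_structural)) {
      kl <- regress_confounds(kl, covs)
      names(kl) <- keys
    }
    list(fc = fc, kl = kl)
  }) -> conn

  # ---- stage: gradients + alignment ---------------------------------------
  run_stage("gradients", {
    log_msg("embedding and aligning gradients")
    ctrl_keys <- keys[key_session == "control"]
    embed <- function(mats) {
      lapply(mats, connectome_gradients, keep_fraction = cfg$keep_fraction,
             alpha = cfg$alpha, diffusion_time = cfg$diffusion_time,
             n_components = cfg$n_components)
    }
    out <- list()
    for (mod in c("fc", "kl")) {
      mats <- conn[[mod]]
      template <- group_template(mats[ctrl_keys], partition,
                                 assoc_network = cfg$assoc_network,
                                 primary_network = cfg$primary_network,
                                 keep_fraction = cfg$keep_fraction,
                                 alpha = cfg$alpha,
                                 diffusion_time = cfg$diffusion_time,
                                 n_components = cfg$n_components)
      aligned <- align_to_template(embed(mats), template)
      prefix <- file.path(cfg$out_dir, paste0("template_", mod))
      write_gradients(template, prefix)
      add_artifact(paste0(prefix, ".tsv"), "tsv", "gradients")
      add_artifact(paste0(prefix, ".json"), "json", "gradients")
      out[[mod]] <- list(template = template, aligned = aligned)
    }
    out
  }) -> grad

  session_scores <- function(mod, sessions) {
    keep <- keys[key_session %in% sessions]
    t(vapply(grad[[mod]]$aligned[keep],
             function(g) g$scores[, 1L], numeric(nrow(partition))))
  }
  net_mat <- function(mod, sessions) {
    keep <- keys[key_session %in% sessions]
    t(vapply(grad[[mod]]$aligned[keep],
             function(g) network_scores(g, partition, 1L),
             numeric(length(unique(partition$network)))))
  }

  # ---- stage: statistics ---------------------------------------------------
  run_stage("stats", {
    log_msg("group statistics")
    spans <- data.frame(
      key = keys, subject = key_subject, session = key_session,
      span_fcg1 = vapply(grad$fc$aligned[keys], gradient_span, numeric(1L)),
      span_stg1 = vapply(grad$kl$aligned[keys], gradient_span, numeric(1L)),
      stringsAsFactors = FALSE)
    utils::write.table(spans, file.path(cfg$out_dir, "spans.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact(file.path(cfg$out_dir, "spans.tsv"), "tsv", "stats")

    span_tests <- do.call(rbind, lapply(c("span_fcg1", "span_stg1"), function(col) {
      ctrl <- spans[spans$session == "control", col]
      pre <- spans[spans$session == "pre", col]
      post <- spans[spans$session == "post", col]
      t1 <- stats::t.test(pre, ctrl)
      t2 <- stats::t.test(pre, post, paired = TRUE)
      data.frame(measure = col,
                 comparison = c("pre_vs_control", "pre_vs_post"),
                 t = c(unname(t1$statistic), unname(t2$statistic)),
                 p = c(t1$p.value, t2$p.value),
                 mean_control = mean(ctrl), mean_pre = mean(pre),
                 mean_post = mean(post), stringsAsFactors = FALSE)
    }))
    utils::write.table(span_tests, file.path(cfg$out_dir, "span_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact(file.path(cfg$out_dir, "span_tests.tsv"), "tsv", "stats")

    roi_stats <- list()
    for (mod in c("fc", "kl")) {
      ctrl <- session_scores(mod, "control")
      pre <- session_scores(mod, "pre")
      post <- session_scores(mod, "post")
      colnames(ctrl) <- colnames(pre) <- colnames(post) <- partition$roi_id
      pre_o <- pre[order(key_subject[key_session == "pre"]), , drop = FALSE]
      post_o <- post[order(key_subject[key_session == "post"]), , drop = FALSE]
      s1 <- roiwise_compare(pre, ctrl, paired = FALSE, q = cfg$q)
      s2 <- roiwise_compare(pre_o, post_o, paired = TRUE, q = cfg$q)
      for (nm in c("pre_vs_control", "pre_vs_post")) {
        s <- if (nm == "pre_vs_control") s1 else s2
        f <- file.path(cfg$out_dir, sprintf("roi_stats_%s_%s.tsv", mod, nm))
        utils::write.table(s, f, sep = "\t", quote = FALSE, row.names = FALSE)
        add_artifact(f, "tsv", "stats")
        roi_stats[[paste(mod, nm, sep = "_")]] <- s
      }
    }
    list(spans = spans, span_tests = span_tests, roi_stats = roi_stats)
  }) -> stats_out

  # ---- stage: classification ----------------------------------------------
  run_stage("classify", {
    log_msg("SVM classification (controls vs patients pre)")
    fcg <- net_mat("fc", c("control", "pre"))
    stg <- net_mat("kl", c("control", "pre"))
    sess <- key_session[key_session %in% c("control", "pre")]
    labels <- factor(ifelse(sess == "control", "control", "patient"),
                     levels = c("control", "patient"))
    reports <- classify(list(FCG1 = fcg, STG1 = stg), labels,
                        folds = cfg$folds, seed = cfg$seed)
    jsonlite::write_json(
      lapply(reports, function(r) r[c("feature_set", "accuracy", "auc",
                                      "cv_scheme")]),
      file.path(cfg$out_dir, "classifier_report.json"),
      auto_unbox = TRUE, digits = NA)
    add_artifact(file.path(cfg$out_dir, "classifier_report.json"),
                 "json", "classify")
    for (nm in names(reports)) {
      f <- file.path(cfg$out_dir, sprintf("roc_%s.tsv", nm))
      utils::write.table(reports[[nm]]$roc_points, f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_artifact(f, "tsv", "classify")
    }
    reports
  }) -> reports

  # ---- stage: treatment correlation ---------------------------------------
  run_stage("correlate", {
    log_msg("gradient-change vs clinical-change correlations")
    pat <- subjects[subjects$group == "patient", ]
    pat <- pat[order(pat$subject_id), ]
    nets <- unique(partition$network)
    cors <- list()
    for (mod in c("fc", "kl")) {
      pre <- net_mat(mod, "pre")
      post <- net_mat(mod, "post")
      ord_pre <- order(key_subject[key_session == "pre"])
      ord_post <- order(key_subject[key_session == "post"])
      dg <- delta_features(pre[ord_pre, , drop = FALSE],
                           post[ord_post, , drop = FALSE])
      du <- delta_clinical(pat)
      covs <- pat[, c("age", "sex")]
      for (net in nets) {
        cors[[paste(mod, net, sep = "_")]] <-
          cbind(modality = mod,
                partial_correlation(dg[, net], du, covs, label = net))
      }
    }
    cors <- do.call(rbind, cors)
    f <- file.path(cfg$out_dir, "treatment_correlations.tsv")
    utils::write.table(cors, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact(f, "tsv", "correlate")
    cors
  }) -> correlations

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("done: ", nrow(manifest), " artifacts in ", cfg$out_dir)

  invisible(list(manifest = manifest, config = cfg, subjects = subjects,
                 partition = partition, truth = truth,
                 connectomes = conn, gradients = grad,
                 stats = stats_out, classifier = reports,
                 correlations = correlations))
}
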