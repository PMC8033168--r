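## Run orchestration and reporting: chains simulate -> segment -> classify
## -> crossmodal over a run directory of TSV/JSON artifacts tracked by a
## YAML manifest, and assembles a static HTML report (tables + inline SVG
## scatter) from whatever stages have completed.

default_config <- function() {
  list(
    cohort = list(n_d0 = 20, n_d4 = 20, noise_sd = 1, height = 40,
                  width = 40, pixel_size = 0.2, cell_radius = 2.8,
                  nucleus_radius = 1.8, effect_786 = 0.8),
    segment = list(k = 10, n_init = 10, subsample = 10000,
                   min_nucleus_um = 3),
    classify = list(compartment = "nucleus", n_keep = 9),
    transcriptome = list(n_transcripts = 2000, n_informative = 30,
                         dispersion = 0.1, counts_file = NULL),
    crossmodal = list(A = 2, n_groups = 3, top_n = 20)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and merges it over the built-in
#' defaults. See `default_config()` in the package source for the full set
#' of keys.
#'
#' @param config Path to a YAML file, a list, or `NULL` for defaults.
#' @return Config list.
#' @export
load_config <- function(config = NULL) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config)
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

stage_done <- function(run_dir, stage) {
  mf <- file.path(run_dir, "run_manifest.yaml")
  if (!file.exists(mf)) return(FALSE)
  stage %in% names(yaml::read_yaml(mf)$stages)
}

update_manifest <- function(run_dir, stage, outputs, seed, config_hash) {
  mf_path <- file.path(run_dir, "run_manifest.yaml")
  mf <- if (file.exists(mf_path)) yaml::read_yaml(mf_path) else
    list(format = "ramanxome-run", version = 1L, seed = seed,
         config_hash = config_hash, stages = list())
  mf$stages[[stage]] <- list(outputs = outputs,
                             timestamp = format(Sys.time(), tz = "UTC"))
  yaml::write_yaml(mf, mf_path)
  invisible(mf)
}

#' Run the full synthetic pipeline into a run directory
#'
#' Stages: `simulate` (cohort + ground truth), `segment` (common k-means,
#' compartment assignment, QC, background subtraction), `classify` (peak
#' ratio, PCA, per-PC tests, LDA, leave-one-out), `crossmodal`
#' (pseudo-replicates, matched transcriptome simulation or counts file,
#' PLS, VIP, leave-one-out prediction). Every stage writes plain-text
#' artifacts and registers them in `run_manifest.yaml`; with
#' `resume = TRUE`, completed stages are skipped.
#'
#' @param config Config list or YAML path (see [load_config()]).
#' @param seed Integer master seed for all randomness.
#' @param out_dir Run directory (created).
#' @param stages Character subset of
#'   `c("simulate", "segment", "classify", "crossmodal")`.
#' @param resume Skip stages already present in the manifest.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = "ramanxome-run",
                         stages = c("simulate", "segment", "classify",
                                    "crossmodal"),
                         resume = FALSE) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  res <- list(config = cfg)

  if ("simulate" %in% stages && !(resume && stage_done(out_dir, "simulate"))) {
    lib <- make_component_library(
      condition_effects = list(D4 = c("nucleus:786" = cfg$cohort$effect_786)))
    geo <- cell_geometry(cfg$cohort$height, cfg$cohort$width,
                         cfg$cohort$pixel_size,
                         cell_radius = cfg$cohort$cell_radius,
                         nucleus_radius = cfg$cohort$nucleus_radius)
    sim <- simulate_cohort(cfg$cohort$n_d0, cfg$cohort$n_d4, lib, geo,
                           noise_sd = cfg$cohort$noise_sd, seed = seed)
    write_cohort(sim$maps, file.path(out_dir, "cohort"), sim$truth,
                 seed = seed)
    res$sim <- sim
    update_manifest(out_dir, "simulate", "cohort", seed, cfg_hash)
  } else if (stage_done(out_dir, "simulate")) {
    co <- read_cohort(file.path(out_dir, "cohort"))
    res$sim <- list(maps = co$maps,
                    truth = list(masks = co$masks,
                                 conditions = vapply(co$maps, `[[`,
                                                     character(1), "condition")))
  }

  if ("segment" %in% stages && !(resume && stage_done(out_dir, "segment"))) {
    seg <- segment_cohort(res$sim$maps, k = cfg$segment$k, seed = seed,
                          n_init = cfg$segment$n_init,
                          subsample = cfg$segment$subsample,
                          min_diameter = cfg$segment$min_nucleus_um)
    cent <- data.table::as.data.table(seg$model$centroids)
    data.table::setnames(cent, sprintf("wn_%g", as.numeric(seg$model$axis)))
    cent <- cbind(data.table::data.table(
      cluster = seq_len(seg$model$k),
      compartment = seg$assignment$mapping), cent)
    write_tsv(cent, file.path(out_dir, "centroids.tsv"))
    write_tsv(seg$qc, file.path(out_dir, "qc.tsv"))
    res$seg <- seg
    update_manifest(out_dir, "segment", c("centroids.tsv", "qc.tsv"),
                    seed, cfg_hash)
  }

  if ("classify" %in% stages && !(resume && stage_done(out_dir, "classify"))) {
    cm <- compartment_matrix(res$seg, cfg$classify$compartment)
    ratio <- peak_ratio_test(cm$spectra, cm$labels, cm$axis)
    pcm <- fit_pca(cm$spectra, n_keep = cfg$classify$n_keep, axis = cm$axis)
    tests <- pc_score_tests(pcm, cm$labels)
    ld <- fit_lda(pcm, cm$labels)
    loo <- loo_classify(cm$spectra, cm$labels, n_keep = cfg$classify$n_keep)
    sc <- data.table::data.table(map_id = rownames(pcm$scores),
                                 condition = cm$labels,
                                 ld_score = ld$scores,
                                 ratio_752_786 = ratio$ratios)
    sc <- cbind(sc, data.table::as.data.table(pcm$scores))
    write_tsv(sc, file.path(out_dir, "scores.tsv"))
    write_tsv(tests, file.path(out_dir, "pc_tests.tsv"))
    write_tsv(data.table::data.table(wavenumber = as.numeric(cm$axis),
                                     loading = ld$loading_spectrum),
              file.path(out_dir, "ld_loading.tsv"))
    jsonlite::write_json(list(confusion = as.list(loo$confusion),
                              sensitivity = loo$sensitivity,
                              specificity = loo$specificity,
                              ratio_p_value = ratio$test$p_value),
                         file.path(out_dir, "classifier.json"),
                         auto_unbox = TRUE, digits = NA)
    res$classify <- list(matrix = cm, ratio = ratio, pcm = pcm,
                         tests = tests, ld = ld, loo = loo)
    update_manifest(out_dir, "classify",
                    c("scores.tsv", "pc_tests.tsv", "ld_loading.tsv",
                      "classifier.json"), seed, cfg_hash)
  }

  if ("crossmodal" %in% stages &&
      !(resume && stage_done(out_dir, "crossmodal"))) {
    pcm <- res$classify$pcm
    labels <- res$classify$matrix$labels
    pseudo <- make_pseudoreplicates(pcm$scores, labels,
                                    cfg$crossmodal$n_groups, seed)
    counts <- if (!is.null(cfg$transcriptome$counts_file)) {
      read_counts(cfg$transcriptome$counts_file)
    } else {
      tx <- simulate_transcriptome(cfg$transcriptome$n_transcripts,
                                   cfg$transcriptome$n_informative,
                                   pseudo$targets,
                                   dispersion = cfg$transcriptome$dispersion,
                                   seed = seed)
      res$tx_truth <- tx$truth
      write_counts(tx$counts, file.path(out_dir, "counts.tsv"))
      tx$counts
    }
    pp <- preprocess_counts(counts, rownames(pseudo$targets))
    full <- fit_pls(pp$features[rownames(pseudo$targets), , drop = FALSE],
                    pseudo$targets, A = cfg$crossmodal$A)
    vip <- vip_scores(full, top_n = cfg$crossmodal$top_n)
    loo <- loo_predict(counts, pseudo$targets, A = cfg$crossmodal$A,
                       ld_model = res$classify$ld)
    write_tsv(vip$ranking, file.path(out_dir, "vip.tsv"))
    write_tsv(cbind(data.table::as.data.table(loo$predictions),
                    data.table::as.data.table(loo$predicted)),
              file.path(out_dir, "predictions.tsv"))
    beta <- data.table::data.table(transcript = rownames(full$beta))
    write_tsv(cbind(beta, data.table::as.data.table(full$beta)),
              file.path(out_dir, "beta.tsv"))
    summary <- list(group_calls = stats::setNames(as.list(loo$predictions$call),
                                                  loo$predictions$sample),
                    calls_correct = sum(loo$predictions$correct),
                    top_n = cfg$crossmodal$top_n)
    if (!is.null(res$tx_truth))
      summary$vip_recovery <- vip_recovery(vip, res$tx_truth,
                                           cfg$crossmodal$top_n)
    jsonlite::write_json(summary, file.path(out_dir, "crossmodal.json"),
                         auto_unbox = TRUE, digits = NA)
    res$crossmodal <- list(pseudo = pseudo, pls = full, vip = vip, loo = loo)
    update_manifest(out_dir, "crossmodal",
                    c("vip.tsv", "predictions.tsv", "beta.tsv",
                      "crossmodal.json"), seed, cfg_hash)
  }
  invisible(res)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 50) {
  df <- utils::head(df, max_rows)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- signif(df[[j]], 5)
  hdr <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                               collapse = ""), "</tr>")
  body <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", html_escape(trimws(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table>", hdr, paste(body, collapse = ""), "</table>")
}

# Minimal inline SVG scatter: x/y numeric, col a CSS color per point,
# crosses for highlighted points (e.g. predicted samples over cells).
svg_scatter <- function(x, y, col, cross = rep(FALSE, length(x)),
                        width = 360, height = 280, pad = 30) {
  rx <- range(x, finite = TRUE); ry <- range(y, finite = TRUE)
  if (diff(rx) == 0) rx <- rx + c(-1, 1)
  if (diff(ry) == 0) ry <- ry + c(-1, 1)
  px <- pad + (x - rx[1]) / diff(rx) * (width - 2 * pad)
  py <- height - pad - (y - ry[1]) / diff(ry) * (height - 2 * pad)
  pts <- vapply(seq_along(x), function(i) {
    if (cross[i])
      sprintf(paste0("<path d='M%.1f %.1f L%.1f %.1f M%.1f %.1f L%.1f %.1f'",
                     " stroke='%s' stroke-width='2'/>"),
              px[i] - 5, py[i] - 5, px[i] + 5, py[i] + 5,
              px[i] - 5, py[i] + 5, px[i] + 5, py[i] - 5, col[i])
    else
      sprintf("<circle cx='%.1f' cy='%.1f' r='3' fill='%s' fill-opacity='0.6'/>",
              px[i], py[i], col[i])
  }, character(1))
  paste0(sprintf("<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d'>",
                 width, height),
         sprintf("<rect width='%d' height='%d' fill='white' stroke='#888'/>",
                 width, height),
         paste(pts, collapse = ""), "</svg>")
}

#' Assemble a static HTML report from a run directory
#'
#' Builds one self-contained HTML document with the QC table, per-PC test
#' table, leave-one-out confusion summary, a predicted-vs-cell PC score
#' scatter, and the VIP top list. Sections whose stage artifacts are
#' missing are marked absent; with `strict = TRUE` a missing stage is an
#' error. The report body is deterministic given the artifacts (no
#' timestamps) and never modifies stage outputs.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @param path Output HTML path (default `report.html` inside `run_dir`).
#' @param strict Error on missing stage outputs.
#' @return The report path, invisibly.
#' @export
build_report <- function(run_dir, path = file.path(run_dir, "report.html"),
                         strict = FALSE) {
  has <- function(f) file.exists(file.path(run_dir, f))
  need <- function(f, section) {
    if (!has(f)) {
      if (strict) stop("missing stage output for section '", section,
                       "': ", f)
      return(NULL)
    }
    file.path(run_dir, f)
  }
  if (!any(vapply(c("qc.tsv", "scores.tsv", "vip.tsv"), has, logical(1))))
    stop("no completed stage outputs found in ", run_dir)
  absent <- "<p class='absent'>section absent (stage not run)</p>"
  sections <- character(0)

  f <- need("qc.tsv", "qc")
  sections <- c(sections, "<h2>Segmentation QC</h2>",
                if (is.null(f)) absent else
                  html_table(data.table::fread(f), max_rows = 200))

  f <- need("pc_tests.tsv", "pc_tests")
  sections <- c(sections, "<h2>Per-PC score tests (Welch)</h2>",
                if (is.null(f)) absent else html_table(data.table::fread(f)))

  f <- need("classifier.json", "classifier")
  sections <- c(sections, "<h2>Leave-one-out classification</h2>",
                if (is.null(f)) absent else {
                  cj <- jsonlite::read_json(f)
                  sprintf(paste0("<p>sensitivity %.1f%%, specificity %.1f%% ",
                                 "(TP %d, FP %d, TN %d, FN %d); ",
                                 "752/786 ratio p = %.3g</p>"),
                          100 * cj$sensitivity, 100 * cj$specificity,
                          cj$confusion$TP, cj$confusion$FP, cj$confusion$TN,
                          cj$confusion$FN, cj$ratio_p_value)
                })

  fs <- need("scores.tsv", "scatter"); fp <- need("predictions.tsv", "scatter")
  sections <- c(sections, "<h2>Predicted vs single-cell PC scores</h2>",
                if (is.null(fs) || is.null(fp)) absent else {
                  sc <- data.table::fread(fs); pr <- data.table::fread(fp)
                  pal <- c(D0 = "#3366cc", D4 = "#cc3333")
                  if (!all(c("PC1", "PC2") %in% names(sc)) ||
                      !all(c("PC1", "PC2") %in% names(pr))) absent else {
                    svg_scatter(c(sc$PC1, pr$PC1), c(sc$PC2, pr$PC2),
                                pal[c(sc$condition, pr$condition)],
                                cross = c(rep(FALSE, nrow(sc)),
                                          rep(TRUE, nrow(pr))))
                  }
                })

  f <- need("vip.tsv", "vip")
  sections <- c(sections, "<h2>Top VIP transcripts</h2>",
                if (is.null(f)) absent else
                  html_table(utils::head(data.table::fread(f), 20)))

  doc <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
           "<title>ramanxome run report</title>",
           "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
           "td,th{border:1px solid #aaa;padding:2px 6px;font-size:12px}",
           ".absent{color:#888;font-style:italic}</style></head><body>",
           "<h1>ramanxome run report</h1>", sections, "</body></html>")
  writeLines(doc, path)
  invisible(path)
}
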