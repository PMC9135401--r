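#' Read a plain-text key-value pipeline configuration
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are kept as strings; consumers split comma lists and coerce
#' numerics. Every numeric default of the pipeline is overridable here.
#'
#' @param path config file path.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, function(m) trimws(m[2]), ""))
}

.cfg <- function(config, key, default = NULL) {
  if (!is.null(config[[key]]) && nzchar(config[[key]])) config[[key]]
  else default
}
.cfg_num <- function(config, key, default) {
  v <- .cfg(config, key)
  if (is.null(v)) default else as.numeric(v)
}
.cfg_vec <- function(config, key, default = NULL) {
  v <- .cfg(config, key)
  if (is.null(v)) default else trimws(strsplit(v, ",")[[1]])
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis graph on a conforming dataset (or a synthetic
#' one): QC, region-versus-rest differential expression, signature selection
#' with reductive subsets, module and cell-cycle scoring with phase
#' distributions and region contrasts, SpatialTime with binned profiles per
#' module, and optional two-group (e.g. young versus aged) comparisons.
#' All artifacts are deterministic CSVs: rerunning with an identical config
#' and seed reproduces them byte for byte. Any stage error aborts with the
#' stage name after marking the output directory incomplete.
#'
#' @param config named list (or path to a [read_config()] file). Recognised
#'   keys include `mode` (`synthetic`/`files`), `out_dir`, `seed`,
#'   `counts_path`/`positions_path`/`regions_path`/`polyline_path` (files
#'   mode), `samples` (synthetic mode, `id:condition` comma list),
#'   `target_region`, `reference_regions`, `min_pct`, `lfc_threshold`,
#'   `k_top`, `size`, `sizes`, `exclude_file`, `module_files`
#'   (`name=path` comma list), `s_genes_file`, `g2m_genes_file`, `n_bins`,
#'   `n_ctrl`, `include_regions`, `profile_bins`, `group_a_samples`,
#'   `group_b_samples`.
#' @param stages character subset of
#'   `c("qc", "de", "signature", "score", "spatialtime")`; default all.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("qc", "de", "signature", "score",
                                    "spatialtime")) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  out_dir <- .cfg(config, "out_dir")
  if (is.null(out_dir)) stop("config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  incomplete <- file.path(out_dir, "_INCOMPLETE")
  file.create(incomplete)
  seed <- as.integer(.cfg_num(config, "seed", 1))
  mode <- .cfg(config, "mode", "synthetic")

  # ---- load or generate the dataset ----
  truth <- NULL
  if (mode == "synthetic") {
    gen <- .stage("generate", {
      samp <- .cfg_vec(config, "samples", "S1:young")
      parts <- strsplit(samp, ":")
      spec <- synthetic_spec(
        samples = data.frame(
          sample_id = vapply(parts, `[[`, "", 1),
          condition = vapply(parts, function(p)
            if (length(p) > 1) p[2] else "young", ""),
          stringsAsFactors = FALSE),
        seed = seed)
      generate_dataset(spec)
    })
    dataset <- gen$dataset
    polylines <- gen$polylines
    truth <- gen
    .stage("generate", {
      write_dataset(dataset, file.path(out_dir, "dataset"))
      write_polylines(polylines, file.path(out_dir, "dataset", "polylines.csv"))
      .write_csv(gen$gene_truth, file.path(out_dir, "truth_genes.csv"))
      .write_csv(gen$spot_truth, file.path(out_dir, "truth_spots.csv"))
    })
  } else if (mode == "files") {
    dataset <- .stage("read", read_dataset(.cfg(config, "counts_path"),
                                           .cfg(config, "positions_path"),
                                           .cfg(config, "regions_path")))
    polylines <- if (!is.null(.cfg(config, "polyline_path")))
      .stage("read", read_polylines(.cfg(config, "polyline_path")))
    else list()
  } else stop("unknown mode '", mode, "'")

  target_region <- .cfg_vec(config, "target_region", "blastema")
  reference_regions <- .cfg_vec(config, "reference_regions")
  known <- unique(dataset$region)
  for (r in c(target_region, reference_regions))
    if (!r %in% known)
      stop("pipeline stage 'de' failed: contrast names undefined region '",
           r, "'", call. = FALSE)

  norm <- .stage("normalize",
                 normalize_log(dataset,
                               .cfg_num(config, "scale_factor", 1e4)))
  prov <- c(
    sprintf("blastemaST %s", as.character(utils::packageVersion("blastemaST"))),
    sprintf("seed = %d", seed), sprintf("mode = %s", mode),
    sprintf("stages = %s", paste(stages, collapse = ",")),
    sprintf("config: %s", {
      keys <- setdiff(names(config), "out_dir")  # path-independent provenance
      paste(sprintf("%s=%s", keys, unlist(config[keys])), collapse = "; ")
    }))

  if ("qc" %in% stages)
    .stage("qc", .write_csv(qc_metrics(dataset), file.path(out_dir, "qc.csv")))

  de <- NULL
  if (any(c("de", "signature") %in% stages)) {
    de <- .stage("de", region_de(
      norm, dataset, target_region, reference_regions,
      min_pct = .cfg_num(config, "min_pct", 0.1),
      lfc_threshold = .cfg_num(config, "lfc_threshold", 0.25)))
    .write_csv(de[, c("gene", "lfc", "p", "p_adj", "pct_in", "pct_out",
                      "specificity")],
               file.path(out_dir, paste0("de_", target_region[1], ".csv")))
  }

  signature <- NULL
  if ("signature" %in% stages) {
    signature <- .stage("signature", {
      exclude <- if (!is.null(.cfg(config, "exclude_file")))
        read_gene_list(.cfg(config, "exclude_file")) else character()
      select_signature(de, k_top = .cfg_num(config, "k_top", 200),
                       size = .cfg_num(config, "size", 100),
                       exclude = exclude)
    })
    .write_csv(as.data.frame(signature), file.path(out_dir, "signature.csv"))
    sizes <- as.integer(.cfg_vec(config, "sizes",
                                 c("100", "50", "25", "10", "5", "1")))
    sizes <- sizes[sizes <= nrow(signature)]
    subsets <- .stage("signature", reduce_signature(signature, sizes))
    .write_csv(data.frame(
      subset = rep(names(subsets), lengths(subsets)),
      rank = unlist(lapply(subsets, seq_along)),
      gene = unlist(subsets)), file.path(out_dir, "signature_subsets.csv"))
  }

  modules <- list()
  if (any(c("score", "spatialtime") %in% stages)) {
    modules <- .stage("score", {
      mf <- .cfg_vec(config, "module_files")
      if (!is.null(mf)) {
        parts <- strsplit(mf, "=")
        stats::setNames(lapply(parts, function(p) read_gene_list(p[2])),
                        vapply(parts, `[[`, "", 1))
      } else if (!is.null(truth)) {
        split(truth$gene_truth$gene, truth$gene_truth$set)[c("signature",
                                                             "gradient")]
      } else if (!is.null(signature)) list(signature = signature$gene)
      else list()
    })
  }

  scores <- list()
  if ("score" %in% stages) {
    sc_rows <- list(); ct_rows <- list()
    for (mname in names(modules)) {
      ms <- .stage("score", module_score(
        norm, modules[[mname]],
        n_bins = .cfg_num(config, "n_bins", 24),
        n_ctrl = .cfg_num(config, "n_ctrl", 100),
        seed = seed + match(mname, names(modules))))
      scores[[mname]] <- ms
      sc_rows[[mname]] <- data.frame(
        module = mname, barcode = names(ms$score),
        sample_id = unname(dataset$sample_id[names(ms$score)]),
        region = unname(dataset$region[names(ms$score)]),
        score = unname(ms$score), stringsAsFactors = FALSE)
      other <- setdiff(known, c(target_region, "unassigned"))
      ct <- .stage("score", score_contrast(ms, dataset, target_region, other))
      ct_rows[[mname]] <- data.frame(module = mname,
                                     mean_diff = ct$mean_diff, p = ct$p,
                                     n_a = ct$n_a, n_b = ct$n_b)
    }
    if (length(sc_rows))
      .write_csv(do.call(rbind, sc_rows), file.path(out_dir,
                                                    "module_scores.csv"))
    if (length(ct_rows))
      .write_csv(do.call(rbind, ct_rows),
                 file.path(out_dir, "module_contrasts.csv"))

    s_genes <- if (!is.null(.cfg(config, "s_genes_file")))
      read_gene_list(.cfg(config, "s_genes_file"))
    else if (!is.null(truth))
      truth$gene_truth$gene[truth$gene_truth$set == "s_phase"]
    g2m_genes <- if (!is.null(.cfg(config, "g2m_genes_file")))
      read_gene_list(.cfg(config, "g2m_genes_file"))
    else if (!is.null(truth))
      truth$gene_truth$gene[truth$gene_truth$set == "g2m_phase"]
    if (!is.null(s_genes) && !is.null(g2m_genes)) {
      cc <- .stage("score", cell_cycle_score(
        norm, s_genes, g2m_genes,
        n_bins = .cfg_num(config, "n_bins", 24),
        n_ctrl = .cfg_num(config, "n_ctrl", 100), seed = seed + 101L))
      .write_csv(as.data.frame(cc), file.path(out_dir, "cell_cycle.csv"))
      .write_csv(phase_distribution(cc, dataset),
                 file.path(out_dir, "phase_distribution.csv"))
    }
  }

  if ("spatialtime" %in% stages && length(polylines)) {
    include_regions <- .cfg_vec(config, "include_regions", "blastema")
    st <- .stage("spatialtime", {
      per_sample <- lapply(polylines, function(p)
        spatial_time(dataset, p, include_regions))
      concatenate_samples(per_sample)
    })
    .write_csv(as.data.frame(st), file.path(out_dir, "spatialtime.csv"))
    if (length(scores)) {
      nb <- as.integer(.cfg_num(config, "profile_bins", 5))
      prof <- do.call(rbind, lapply(names(scores), function(mname)
        cbind(module = mname,
              binned_profile(st, scores[[mname]], n_bins = nb))))
      .write_csv(prof, file.path(out_dir, "profiles.csv"))
      ga <- .cfg_vec(config, "group_a_samples")
      gb <- .cfg_vec(config, "group_b_samples")
      if (!is.null(ga) && !is.null(gb)) {
        cmp <- do.call(rbind, lapply(names(scores), function(mname) {
          v <- scores[[mname]]$score[st$barcode]
          ina <- st$sample_id %in% ga; inb <- st$sample_id %in% gb
          data.frame(module = mname,
                     mean_a = mean(v[ina]), mean_b = mean(v[inb]),
                     mean_diff = mean(v[ina]) - mean(v[inb]),
                     p = rank_sum_test(v[ina], v[inb]),
                     n_a = sum(ina), n_b = sum(inb))
        }))
        .write_csv(cmp, file.path(out_dir, "group_comparison.csv"))
      }
    }
  }

  writeLines(prov, file.path(out_dir, "provenance.txt"))
  file.remove(incomplete)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin wrapper used by `inst/cli/blastemaST.R`. Subcommands map onto
#' [run_pipeline()] stages: `generate`, `qc`, `de`, `signature`, `score`,
#' `spatialtime`, `run` (everything). Common flags: `--config PATH`
#' (required), `--seed INT`, `--out DIR`, `--log-level LEVEL`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the output directory.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: blastemaST.R <generate|qc|de|signature|score|spatialtime|run> ",
            "--config PATH [--seed INT] [--out DIR] [--log-level LEVEL]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  config <- if (!is.null(opts$config)) read_config(opts$config) else list()
  if (!is.null(opts$seed)) config$seed <- opts$seed
  if (!is.null(opts$out)) config$out_dir <- opts$out
  stage_map <- list(generate = character(0), qc = "qc", de = "de",
                    signature = c("de", "signature"),
                    score = "score", spatialtime = c("score", "spatialtime"),
                    run = c("qc", "de", "signature", "score", "spatialtime"))
  if (is.null(stage_map[[cmd]])) stop("unknown subcommand '", cmd, "'")
  if (!is.null(opts[["log-level"]]) &&
      identical(tolower(opts[["log-level"]]), "debug"))
    message("running '", cmd, "' with config keys: ",
            paste(names(config), collapse = ", "))
  run_pipeline(config, stages = stage_map[[cmd]])
}
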