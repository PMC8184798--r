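#' @include synthetic-data.R mutation-profiling.R reactivity.R differential.R
#' @include folding.R clustering.R dicer-rules.R pdb-io.R sam-io.R
NULL

#' Default pipeline configuration
#'
#' Every stage parameter with its default: masking coverage 1000x, DMSO
#' background ceiling 0.05, merge spacer 2, pseudo-energy slope 1.8 and
#' intercept -0.6, replicate-QC windows of 50 nt stepped by 10 with coverage
#' cutoffs 500..5000, K = 3 clusters, and the 59 +/- 1 Angstrom distance
#' rule. The \code{simulate} block sizes the synthetic inputs when the
#' pipeline generates its own data.
#'
#' @param seed Integer seed used (with fixed per-stage offsets) by every
#'   stochastic stage.
#' @param out_dir Output directory.
#' @return Configuration list.
#' @export
defaultConfig <- function(seed = 1L, out_dir = "icshapemap_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(enabled = TRUE, n_transcripts = 8L, stem_len = 15L,
                    loop_len = 9L, mod_rate_ss = 0.02, mod_rate_ds = 0.002,
                    background_rate = 0.002, depth = 400L,
                    n_count_transcripts = 30L, count_total = 100000L,
                    helix_bp = 22L, n_models = 10L, model_jitter_sd = 0.5),
    inputs = list(nai_sam = NULL, nai2_sam = NULL, dmso_sam = NULL,
                  dmso2_sam = NULL, ref_fasta = NULL, rip_tsv = NULL,
                  input_tsv = NULL, dead_tsv = NULL, wt_tsv = NULL,
                  annot_tsv = NULL, pdb_dir = NULL, structures = NULL),
    params = list(min_coverage = 1000L, max_background = 0.05,
                  merge_spacer = 2L, min_mapq = 1L,
                  slope = 1.8, intercept = -0.6,
                  window = 50L, step = 10L,
                  cutoffs = c(500, 1000, 2000, 3000, 4000, 5000),
                  k = 3L, target = 59, tol = 1)
  )
}

#' @rdname defaultConfig
#' @param path Optional path to write the JSON defaults dump to.
#' @export
printConfig <- function(path = NULL, seed = 1L) {
  cfg <- defaultConfig(seed = seed)
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) cat(js, "\n") else writeLines(js, path)
  invisible(cfg)
}

#' Read a pipeline configuration from JSON
#'
#' Unspecified fields fall back to \code{\link{defaultConfig}}.
#'
#' @param path JSON config path.
#' @return Configuration list.
#' @export
readConfig <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- defaultConfig()
  merge2 <- function(b, u) {
    for (nm in names(u)) {
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(u[[nm]]))
        merge2(b[[nm]], u[[nm]]) else u[[nm]]
    }
    b
  }
  merge2(base, user)
}

configHash <- function(config) {
  # hash the analysis-determining fields only: where the run lands on disk
  # must not change what it computes
  core <- config[c("seed", "simulate", "params")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

outputHeader <- function(config) {
  sprintf("# icShapeMaP %s config=%s seed=%d",
          as.character(utils::packageVersion("icShapeMaP")),
          configHash(config), config$seed)
}

writeStageTsv <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

simulateInputs <- function(config, dir) {
  sim <- config$simulate
  p <- config$params
  spec <- simSpec(n_transcripts = sim$n_transcripts, stem_len = sim$stem_len,
                  loop_len = sim$loop_len, mod_rate_ss = sim$mod_rate_ss,
                  mod_rate_ds = sim$mod_rate_ds,
                  background_rate = sim$background_rate, depth = sim$depth,
                  seed = config$seed)
  hp <- makeHairpinSet(spec)
  refs <- stats::setNames(hp$sequence, hp$id)
  writeReferenceFasta(refs, file.path(dir, "references.fasta"))
  writeDotBracket(stats::setNames(
    lapply(seq_len(nrow(hp)), function(i)
      secondaryStructure(hp$sequence[i], hp$structure[i])), hp$id),
    file.path(dir, "true_structures.db"))
  libs <- list(nai_sam = c("NAI", 1L), nai2_sam = c("NAI", 2L),
               dmso_sam = c("DMSO", 3L), dmso2_sam = c("DMSO", 4L))
  for (nm in names(libs)) {
    cond <- libs[[nm]][1]
    off <- as.integer(libs[[nm]][2])
    allReads <- do.call(rbind, lapply(seq_len(nrow(hp)), function(i) {
      r <- simulateMapReads(hp$sequence[i], hp$structure[i], spec,
                            condition = cond,
                            seed = config$seed * 1000L + i * 10L + off)
      r$rname <- hp$id[i]
      r$qname <- paste0(hp$id[i], "_", r$qname)
      r
    }))
    writeSamReads(allReads, nchar(refs), file.path(dir, paste0(nm, ".sam")))
  }
  nT <- sim$n_count_transcripts
  effects <- rep(0, nT)
  effects[seq_len(floor(nT / 3))] <-
    rep(c(1, 2, -1, 1.5), length.out = floor(nT / 3))
  for (pair in list(c("rip_tsv", "input_tsv", 7L), c("dead_tsv", "wt_tsv", 8L))) {
    tab <- simulateCountTables(nT, effects, sim$count_total,
                               seed = config$seed * 100L + as.integer(pair[3]))
    writeStageTsv(data.frame(transcript = tab$transcript, count = tab$count_b),
                  file.path(dir, paste0(pair[1], ".tsv")), outputHeader(config))
    writeStageTsv(data.frame(transcript = tab$transcript, count = tab$count_a),
                  file.path(dir, paste0(pair[2], ".tsv")), outputHeader(config))
    utils::write.table(tab, file.path(dir, paste0("truth_", pair[1], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # synthetic pre-miRNA duplexes with jittered-helix model ensembles
  nb <- sim$helix_bp
  pdbDir <- file.path(dir, "models")
  dir.create(pdbDir, showWarnings = FALSE)
  annot <- list(); structs <- list()
  set.seed(config$seed * 100L + 9L)
  for (m in seq_len(3)) {
    id <- sprintf("synmir_%02d", m)
    seqlen <- 2L * nb
    sq <- paste(sample(RNA_BASES, seqlen, replace = TRUE), collapse = "")
    db <- paste0(strrep("(", nb - 2L), "....", strrep(")", nb - 2L))
    annot[[id]] <- mirnaAnnotation(id, sq, c(1L, nb - 3L),
                                   c(nb + 4L, seqlen))
    structs[[id]] <- secondaryStructure(sq, db)
    base <- buildHelixCoordinates(helixSpec(nb), energy = 0)
    models <- lapply(seq_len(sim$n_models), function(k) {
      mm <- jitterModel(base, sd = sim$model_jitter_sd)
      mm@energy <- as.numeric(k)
      mm
    })
    writePdbModels(models, file.path(pdbDir, paste0(id, ".pdb")))
  }
  annotTab <- do.call(rbind, lapply(annot, function(a)
    data.frame(id = a@id, sequence = a@sequence,
               start_5p = a@span5p[1], end_5p = a@span5p[2],
               start_3p = a@span3p[1], end_3p = a@span3p[2],
               stringsAsFactors = FALSE)))
  utils::write.table(annotTab, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeDotBracket(structs, file.path(dir, "mir_structures.db"))
  list(nai_sam = file.path(dir, "nai_sam.sam"),
       nai2_sam = file.path(dir, "nai2_sam.sam"),
       dmso_sam = file.path(dir, "dmso_sam.sam"),
       dmso2_sam = file.path(dir, "dmso2_sam.sam"),
       ref_fasta = file.path(dir, "references.fasta"),
       rip_tsv = file.path(dir, "rip_tsv.tsv"),
       input_tsv = file.path(dir, "input_tsv.tsv"),
       dead_tsv = file.path(dir, "dead_tsv.tsv"),
       wt_tsv = file.path(dir, "wt_tsv.tsv"),
       annot_tsv = file.path(dir, "annotations.tsv"),
       pdb_dir = pdbDir,
       structures = file.path(dir, "mir_structures.db"),
       true_structures = file.path(dir, "true_structures.db"))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order (simulate or validate inputs,
#' profile, score, QC, differential, fold, cluster, rules) inside
#' \code{config$out_dir}. Every tabular output carries a header line with
#' the package version, config hash and seed; reruns with the same config
#' and seed are byte-identical. On a stage failure, completed outputs are
#' left in place and a machine-readable \code{error.json} is written before
#' the error propagates.
#'
#' @param config Configuration list (see \code{\link{defaultConfig}} /
#'   \code{\link{readConfig}}).
#' @return The run directory path, invisibly.
#' @export
runPipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$out_dir, "run.log")
  cat("icShapeMaP run, seed", config$seed, "config", configHash(config), "\n",
      file = logFile)
  logmsg <- function(...) {
    msg <- paste(...)
    cat(msg, "\n", file = logFile, append = TRUE)
    message(msg)
  }
  hdr <- outputHeader(config)
  p <- config$params
  stage <- function(name, fn) {
    logmsg("stage:", name)
    tryCatch(fn(), error = function(e) {
      jsonlite::write_json(list(stage = name, error = conditionMessage(e)),
                           file.path(config$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  # -- inputs
  inputs <- NULL
  stage("inputs", function() {
    if (isTRUE(config$simulate$enabled)) {
      inDir <- file.path(config$out_dir, "inputs")
      dir.create(inDir, showWarnings = FALSE)
      inputs <<- simulateInputs(config, inDir)
    } else {
      inputs <<- config$inputs
      need <- c("nai_sam", "dmso_sam", "ref_fasta")
      for (nm in need)
        if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]]))
          stop("missing required input: ", nm)
    }
  })
  refs <- readReferenceFasta(inputs$ref_fasta)
  # -- profile
  countsByLib <- list()
  stage("profile", function() {
    for (lib in c("nai_sam", "nai2_sam", "dmso_sam", "dmso2_sam")) {
      if (is.null(inputs[[lib]]) || !file.exists(inputs[[lib]])) next
      countsByLib[[lib]] <<- profileSam(inputs[[lib]], inputs$ref_fasta,
                                        minMapq = p$min_mapq,
                                        mergeSpacer = p$merge_spacer)
      writeMutationCountsTsv(countsByLib[[lib]],
                             file.path(config$out_dir,
                                       paste0("counts_", lib, ".tsv")))
    }
  })
  # -- score
  profiles <- list()
  stage("score", function() {
    naiL <- countsByLib[c("nai_sam", "nai2_sam")]
    dmsoL <- countsByLib[c("dmso_sam", "dmso2_sam")]
    naiL <- naiL[!vapply(naiL, is.null, TRUE)]
    dmsoL <- dmsoL[!vapply(dmsoL, is.null, TRUE)]
    for (id in names(refs)) {
      profiles[[id]] <<- scoreTranscript(
        lapply(naiL, `[[`, id), lapply(dmsoL, `[[`, id),
        sequence = refs[[id]], minCoverage = p$min_coverage,
        maxBackground = p$max_background)
    }
    writeProfileTsv(profiles, file.path(config$out_dir, "reactivity.tsv"))
    shapeDir <- file.path(config$out_dir, "shape")
    dir.create(shapeDir, showWarnings = FALSE)
    for (id in names(profiles))
      writeShapeFile(profiles[[id]], file.path(shapeDir, paste0(id, ".shape")))
  })
  # -- qc (optional: needs two NAI replicates)
  stage("qc", function() {
    if (is.null(countsByLib$nai2_sam)) {
      logmsg("qc: skipped (single NAI replicate)")
      return()
    }
    rc <- replicateCorrelation(countsByLib$nai_sam, countsByLib$nai2_sam,
                               window = p$window, step = p$step,
                               cutoffs = p$cutoffs, seed = config$seed)
    med <- vapply(rc, function(x) if (length(x)) stats::median(x) else NA_real_,
                  1.0)
    writeStageTsv(data.frame(cutoff = as.numeric(names(rc)),
                             n_windows = vapply(rc, length, 1L),
                             median_r = med),
                  file.path(config$out_dir, "qc_replicates.tsv"), hdr)
    rcPlain <- rc
    attr(rcPlain, "skipped") <- NULL
    jsonlite::write_json(rcPlain, file.path(config$out_dir, "qc_windows.json"),
                         auto_unbox = FALSE, digits = NA)
  })
  # -- differential
  stage("diff", function() {
    if (!is.null(inputs$rip_tsv))
      writeStageTsv(scoreCountTables(inputs$rip_tsv, inputs$input_tsv),
                    file.path(config$out_dir, "enrichment.tsv"), hdr)
    if (!is.null(inputs$dead_tsv))
      writeStageTsv(scoreCountTables(inputs$dead_tsv, inputs$wt_tsv),
                    file.path(config$out_dir, "cleavage.tsv"), hdr)
  })
  # -- fold
  folded <- list()
  stage("fold", function() {
    pep <- pseudoEnergyParams(slope = p$slope, intercept = p$intercept)
    model <- energyModel(maxLen = max(nchar(refs)))
    for (id in names(refs))
      folded[[id]] <<- foldConstrained(refs[[id]], profiles[[id]], pep, model)
    writeDotBracket(folded, file.path(config$out_dir, "folded.db"))
    if (!is.null(inputs$true_structures)) {
      truth <- readDotBracket(inputs$true_structures)
      rows <- lapply(names(folded), function(id) {
        cmp <- compareStructures(folded[[id]], truth[[id]])
        auc <- tryCatch(structureAuc(profiles[[id]], truth[[id]]),
                        error = function(e) NA_real_)
        data.frame(transcript = id, auc = auc,
                   identical = sum(cmp == "identical"),
                   different = sum(cmp != "identical"),
                   stringsAsFactors = FALSE)
      })
      writeStageTsv(do.call(rbind, rows),
                    file.path(config$out_dir, "structure_eval.tsv"), hdr)
    }
  })
  # -- cluster
  stage("cluster", function() {
    res <- clusterProfiles(profiles, folded, k = min(p$k, length(profiles)),
                           seed = config$seed)
    writeStageTsv(data.frame(transcript = rownames(res$coords), res$coords,
                             cluster = res$labels),
                  file.path(config$out_dir, "cluster_coords.tsv"), hdr)
    writeStageTsv(data.frame(position = rownames(res$loadings), res$loadings),
                  file.path(config$out_dir, "cluster_loadings.tsv"), hdr)
  })
  # -- rules
  stage("rules", function() {
    if (is.null(inputs$annot_tsv)) return()
    annots <- readMirnaAnnotationTsv(inputs$annot_tsv)
    structs <- readDotBracket(inputs$structures)
    modelSets <- lapply(names(annots), function(id)
      readPdbModels(file.path(inputs$pdb_dir, paste0(id, ".pdb"))))
    names(modelSets) <- names(annots)
    writeStageTsv(ruleTable(modelSets, annots, structs,
                            target = p$target, tol = p$tol),
                  file.path(config$out_dir, "rules.tsv"), hdr)
  })
  # -- manifest
  outs <- list.files(config$out_dir, pattern = "\\.(tsv|db|json|shape)$",
                     recursive = TRUE, full.names = TRUE)
  outs <- outs[basename(outs) != "manifest.tsv"]
  sums <- tools::md5sum(sort(outs))
  utils::write.table(
    data.frame(file = sub(paste0("^", config$out_dir, "/?"), "", names(sums)),
               md5 = unname(sums)),
    file.path(config$out_dir, "manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  logmsg("pipeline complete")
  invisible(config$out_dir)
}

#' Summarize a pipeline run
#'
#' Verifies the run manifest (flagging checksum mismatches), tabulates
#' per-transcript AUCs, enrichment/cleavage summaries, cluster sizes and
#' the rule Venn counts into \code{report.md}, and renders the cumulative
#' replicate-correlation curves and the cluster scatter into
#' \code{report.pdf}. Absent optional stages are marked absent, not errors.
#'
#' @param runDir Directory produced by \code{\link{runPipeline}}.
#' @return List with the report path and the names of any files whose
#'   checksum no longer matches the manifest.
#' @export
writeReport <- function(runDir) {
  if (!dir.exists(runDir) || !file.exists(file.path(runDir, "manifest.tsv")))
    stop("not a pipeline run directory: ", runDir)
  man <- utils::read.table(file.path(runDir, "manifest.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  cur <- tools::md5sum(file.path(runDir, man$file))
  bad <- man$file[is.na(cur) | cur != man$md5]
  lines <- c("# icShapeMaP run report", "")
  if (length(bad))
    lines <- c(lines, "**CHECKSUM MISMATCH** in:", paste(" -", bad), "")
  readTsv <- function(f) {
    path <- file.path(runDir, f)
    if (!file.exists(path)) return(NULL)
    tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE),
             error = function(e) NULL)   # corrupt files are already flagged
  }
  se <- readTsv("structure_eval.tsv")
  if (!is.null(se)) {
    lines <- c(lines, "## Structure evaluation",
               sprintf("- mean AUC: %.3f over %d transcripts",
                       mean(se$auc, na.rm = TRUE), nrow(se)),
               sprintf("- %s: AUC %.3f, %d/%d positions identical to truth",
                       se$transcript, se$auc, se$identical,
                       se$identical + se$different), "")
  }
  for (f in c("enrichment.tsv", "cleavage.tsv")) {
    d <- readTsv(f)
    if (!is.null(d))
      lines <- c(lines, paste0("## ", sub(".tsv", "", f)),
                 sprintf("- %d transcripts scored, %d enriched (score > 0)",
                         nrow(d), sum(d$enriched, na.rm = TRUE)), "")
  }
  cl <- readTsv("cluster_coords.tsv")
  if (!is.null(cl)) {
    sizes <- table(cl$cluster)
    lines <- c(lines, "## Clusters",
               sprintf("- cluster %s: %d transcripts",
                       names(sizes), as.integer(sizes)), "")
  }
  ru <- readTsv("rules.tsv")
  if (!is.null(ru)) {
    venn <- table(factor(ru$venn_cell,
                         levels = apply(expand.grid(0:1, 0:1, 0:1), 1,
                                        paste0, collapse = "")))
    lines <- c(lines, "## Dicer cleavage rules (loop / 3' / 5')",
               sprintf("- cell %s: %d", names(venn), as.integer(venn)), "")
  }
  qc <- readTsv("qc_replicates.tsv")
  if (is.null(qc)) lines <- c(lines, "## Replicate QC", "- absent", "")
  writeLines(lines, file.path(runDir, "report.md"))
  grDevices::pdf(file.path(runDir, "report.pdf"), width = 8, height = 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  if (file.exists(file.path(runDir, "qc_windows.json"))) {
    rc <- jsonlite::read_json(file.path(runDir, "qc_windows.json"),
                              simplifyVector = TRUE)
    graphics::plot(NULL, xlim = c(-1, 1), ylim = c(0, 1),
                   xlab = "window Pearson r", ylab = "cumulative fraction",
                   main = "Replicate correlation")
    cols <- grDevices::rainbow(length(rc))
    for (i in seq_along(rc)) {
      x <- sort(unlist(rc[[i]]))
      if (length(x))
        graphics::lines(x, seq_along(x) / length(x), col = cols[i])
    }
    graphics::legend("topleft", legend = names(rc), col = cols, lty = 1,
                     cex = 0.6)
  }
  if (!is.null(cl))
    graphics::plot(cl$PC1, cl$PC2, col = cl$cluster, pch = 19,
                   xlab = "PC1", ylab = "PC2", main = "Profile clusters")
  list(report = file.path(runDir, "report.md"), checksum_mismatch = bad)
}
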