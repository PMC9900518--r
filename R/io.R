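#' Write a z-stack as a multi-page TIFF
#'
#' One page per plane, quantized to 16-bit: intensities are rounded,
#' clamped to `[0, maxADU]` and stored as `value / maxADU`. Reading the
#' file back with [readStack()] recovers the rounded intensities exactly.
#'
#' @param stack a \linkS4class{ZStack}.
#' @param path output file (`.tif`).
#' @param maxADU full-scale intensity mapped to 16-bit white (default
#'   65535, i.e. unit gain).
#' @return invisibly, `path`.
#' @export
writeStack <- function(stack, path, maxADU = 65535) {
  stopifnot(is(stack, "ZStack"))
  d <- imgData(stack)
  pages <- lapply(seq_len(dim(d)[3]), function(k) {
    pmin(pmax(round(d[, , k]), 0), maxADU) / maxADU
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read multi-page TIFF z-stacks
#'
#' Reads a multi-page TIFF and splits its pages into one or more
#' channel stacks according to the declared layout. Pages must divide
#' evenly into `nChannels`; with `interleaved = FALSE` (default) the
#' file holds each channel's planes as a contiguous block, with
#' `interleaved = TRUE` pages cycle through the channels plane by plane.
#' Intensities are returned as real values on the `[0, maxADU]` scale.
#'
#' @param path TIFF file.
#' @param nChannels number of channels stored in the file (default 1).
#' @param channelNames optional channel labels.
#' @param interleaved page ordering, see above.
#' @param maxADU intensity scale (must match the writer's).
#' @param planeSpacing optional axial spacing metadata, micrometres.
#' @return a \linkS4class{ZStack} if `nChannels == 1`, else a named list
#'   of them.
#' @export
readStack <- function(path, nChannels = 1L, channelNames = NULL,
                      interleaved = FALSE, maxADU = 65535,
                      planeSpacing = NA_real_) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nChannels <- as.integer(nChannels)
  if (length(pages) %% nChannels != 0L) {
    stop(
      "layout mismatch in ", path, ": ", length(pages),
      " page(s) not divisible into ", nChannels, " channel(s)"
    )
  }
  np <- length(pages) %/% nChannels
  if (is.null(channelNames)) {
    channelNames <- if (nChannels == 1L) "" else paste0("ch", seq_len(nChannels))
  }
  out <- vector("list", nChannels)
  for (ch in seq_len(nChannels)) {
    idx <- if (interleaved) {
      seq(ch, length(pages), by = nChannels)
    } else {
      seq((ch - 1L) * np + 1L, ch * np)
    }
    a <- array(0, c(dim(pages[[1]])[1:2], np))
    for (k in seq_len(np)) {
      pg <- pages[[idx[k]]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1] # greyscale written as RGB
      a[, , k] <- pg * maxADU
    }
    out[[ch]] <- ZStack(a,
      planeSpacing = planeSpacing,
      channelName = channelNames[ch]
    )
  }
  names(out) <- channelNames
  if (nChannels == 1L) out[[1]] else out
}

#' Write a simulated scene to a field directory
#'
#' Writes `<fieldId>_nuclear.tif` and `<fieldId>_foci.tif` (16-bit
#' multi-page TIFFs) plus the ground-truth sidecar
#' `<fieldId>_truth.json` and `<fieldId>_labels.tif`, the on-disk layout
#' [runFociPipeline()] consumes.
#'
#' @param scene result of [simulateScene()].
#' @param dir output directory (created if needed).
#' @param fieldId field name used as the file prefix.
#' @return invisibly, the paths written.
#' @export
writeScene <- function(scene, dir, fieldId = "field01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pn <- file.path(dir, paste0(fieldId, "_nuclear.tif"))
  pf <- file.path(dir, paste0(fieldId, "_foci.tif"))
  writeStack(scene$nuclear, pn)
  writeStack(scene$foci, pf)
  truth <- scene$truth
  pj <- file.path(dir, paste0(fieldId, "_truth.json"))
  jsonlite::write_json(
    list(
      nuclei = nucleusRecords(truth),
      foci = plantedFoci(truth)
    ),
    pj,
    digits = NA, auto_unbox = TRUE
  )
  pl <- file.path(dir, paste0(fieldId, "_labels.tif"))
  tiff::writeTIFF(labelImage(truth) / 65535, pl, bits.per.sample = 16L)
  invisible(c(pn, pf, pj, pl))
}

#' Read a pipeline configuration from JSON
#'
#' The JSON may hold `scene`, `segmentation`, `foci` and `filter`
#' sections (each passed to the matching constructor — [sceneConfig()],
#' [segmentationConfig()], [fociConfig()]; `filter` holds
#' `sigmaSpatial`, `sigmaRange`, `radius` for the bilateral stage), plus
#' optional top-level `seed`.
#'
#' @param path JSON file.
#' @return list with validated `scene`, `segmentation`, `foci`,
#'   `filter`, `seed` components (defaults where a section is absent).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  asArgs <- function(x) if (is.null(x)) list() else as.list(x)
  list(
    scene = do.call(sceneConfig, asArgs(js$scene)),
    segmentation = do.call(segmentationConfig, asArgs(js$segmentation)),
    foci = do.call(fociConfig, asArgs(js$foci)),
    filter = utils::modifyList(
      list(sigmaSpatial = 2, sigmaRange = NULL, radius = NULL),
      asArgs(js$filter)
    ),
    seed = if (is.null(js$seed)) 1L else as.integer(js$seed)
  )
}

#' Process one imaged field
#'
#' The per-field composition of the imaging stages: bilateral-smooth
#' every plane of both channels, project (MIP), normalize to `[0, 1]`,
#' segment nuclei on the nuclear channel and detect foci on the foci
#' channel. If the raw (pre-normalization) dynamic range of the foci MIP
#' is below `fociCfg$minDynamicRange`, the field is treated as blank:
#' the nuclei are still reported, with zero foci.
#'
#' @param nuclear,foci \linkS4class{ZStack}s of the two channels.
#' @param segCfg a [segmentationConfig()] list.
#' @param fociCfg a [fociConfig()] list.
#' @param filter list with `sigmaSpatial`, `sigmaRange`, `radius` for
#'   [bilateralFilter()].
#' @return list with `nuclei` (\linkS4class{LabeledNuclei}) and
#'   `foci` (\linkS4class{FociSet}).
#' @export
processField <- function(nuclear, foci, segCfg = segmentationConfig(),
                         fociCfg = fociConfig(),
                         filter = list(
                           sigmaSpatial = 2, sigmaRange = NULL,
                           radius = NULL
                         )) {
  stopifnot(is(nuclear, "ZStack"), is(foci, "ZStack"))
  if (!identical(dim(imgData(nuclear)), dim(imgData(foci)))) {
    stop("nuclear and foci stacks have different shapes")
  }
  sm <- function(st) {
    smoothStack(st, filter$sigmaSpatial, filter$sigmaRange, filter$radius)
  }
  mipN <- maxIntensityProjection(sm(nuclear))
  mipF <- maxIntensityProjection(sm(foci))
  nuclei <- segmentNuclei(normalize01(mipN), segCfg)
  rawRange <- diff(range(imgData(mipF)))
  if (rawRange < fociCfg$minDynamicRange) {
    counts <- rep(0L, nucleusCount(nuclei))
    names(counts) <- as.character(seq_len(nucleusCount(nuclei)))
    fociSet <- new("FociSet",
      foci = data.frame(
        id = integer(), cy = numeric(), cx = numeric(),
        area = integer(), peak = numeric(), nucleus = integer()
      ),
      perNucleusCounts = counts
    )
  } else {
    fociSet <- detectFoci(normalize01(mipF), nuclei, fociCfg)
  }
  list(nuclei = nuclei, foci = fociSet)
}

# read the *_nuclear.tif / *_foci.tif pairs of one well directory
wellFields <- function(dir) {
  nuc <- sort(list.files(dir, pattern = "_nuclear\\.tif$"))
  if (!length(nuc)) {
    stop("no *_nuclear.tif fields found in well directory: ", dir)
  }
  ids <- sub("_nuclear\\.tif$", "", nuc)
  foc <- file.path(dir, paste0(ids, "_foci.tif"))
  missing <- !file.exists(foc)
  if (any(missing)) {
    stop(
      "missing foci channel for field(s): ",
      paste(ids[missing], collapse = ", "), " in ", dir
    )
  }
  data.frame(
    field = ids, nuclear = file.path(dir, nuc), foci = foc,
    stringsAsFactors = FALSE
  )
}

processWell <- function(dir, wellId, segCfg, fociCfg, filter) {
  fields <- wellFields(dir)
  sets <- vector("list", nrow(fields))
  perNuc <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    nuclear <- readStack(fields$nuclear[i], channelNames = "nuclear")
    foci <- readStack(fields$foci[i], channelNames = "foci")
    res <- tryCatch(
      processField(nuclear, foci, segCfg, fociCfg, filter),
      error = function(e) {
        stop(
          "well ", wellId, ", field ", fields$field[i], ": ",
          conditionMessage(e),
          call. = FALSE
        )
      }
    )
    sets[[i]] <- res$foci
    rec <- nucleusRecords(res$nuclei)
    cnt <- fociCounts(res$foci)
    perNuc[[i]] <- if (nrow(rec)) {
      data.frame(
        well = wellId, field = fields$field[i], nucleus = rec$id,
        area = rec$area, cy = rec$cy, cx = rec$cx,
        fociCount = as.integer(cnt[as.character(rec$id)])
      )
    } else {
      data.frame(
        well = character(), field = character(), nucleus = integer(),
        area = integer(), cy = numeric(), cx = numeric(),
        fociCount = integer()
      )
    }
  }
  list(
    summary = summarizeWell(sets, wellId, fieldIds = fields$field),
    perNucleus = do.call(rbind, perNuc)
  )
}

#' Run the foci-counting pipeline over baseline and treated wells
#'
#' End-to-end composition of the imaging stages for a
#' baseline-vs-treatment experiment. Each well is a directory of
#' `<field>_nuclear.tif` / `<field>_foci.tif` pairs (see [writeScene()]).
#' Per-nucleus, per-field and per-well tables are written as CSV along
#' with the fold-change table (treated over baseline, paired by
#' position; a single baseline well is recycled). A plain-text log
#' records every parameter used; timestamps are confined to the log so
#' repeated runs produce byte-identical CSVs.
#'
#' @param baselineDirs character vector of baseline well directories.
#' @param treatedDirs character vector of treated well directories.
#' @param outDir output directory for the CSV report tables.
#' @param segCfg,fociCfg,filter stage configurations as in
#'   [processField()].
#' @return invisibly, a list with `perNucleus`, `perField`, `perWell`
#'   and `foldChange` data.frames (also written to `outDir`).
#' @export
runFociPipeline <- function(baselineDirs, treatedDirs, outDir,
                            segCfg = segmentationConfig(),
                            fociCfg = fociConfig(),
                            filter = list(
                              sigmaSpatial = 2, sigmaRange = NULL,
                              radius = NULL
                            )) {
  if (!length(baselineDirs)) {
    stop("fold change requires at least one baseline well")
  }
  if (!length(treatedDirs)) stop("need at least one treated well")
  if (length(baselineDirs) == 1L && length(treatedDirs) > 1L) {
    baselineDirs <- rep(baselineDirs, length(treatedDirs))
  }
  if (length(baselineDirs) != length(treatedDirs)) {
    stop("baseline and treated well lists must pair up")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  runSet <- function(dirs, condition) {
    lapply(seq_along(dirs), function(i) {
      w <- processWell(
        dirs[i], sprintf("%s%02d", condition, i),
        segCfg, fociCfg, filter
      )
      w$condition <- condition
      w
    })
  }
  base <- runSet(unique(baselineDirs), "baseline")
  # map recycled baselines back to their unique run
  baseIdx <- match(baselineDirs, unique(baselineDirs))
  trt <- runSet(treatedDirs, "treated")

  collect <- function(runs, what) {
    do.call(rbind, lapply(runs, function(w) {
      if (what == "perNucleus") {
        if (nrow(w$perNucleus)) {
          cbind(condition = w$condition, w$perNucleus)
        } else {
          NULL
        }
      } else {
        s <- w$summary
        pf <- s@perField
        if (what == "perField") {
          data.frame(
            condition = w$condition, well = wellId(s), field = pf$field,
            nNuclei = pf$nNuclei, nFoci = pf$nFoci,
            meanFociPerNucleus = ifelse(pf$nNuclei > 0,
              pf$nFoci / pf$nNuclei, NA_real_
            )
          )
        } else {
          data.frame(
            condition = w$condition, well = wellId(s),
            nNuclei = s@nNuclei, nFoci = s@nFoci,
            meanFociPerNucleus = meanFociPerNucleus(s)
          )
        }
      }
    }))
  }
  allRuns <- c(base, trt)
  perNucleus <- collect(allRuns, "perNucleus")
  perField <- collect(allRuns, "perField")
  perWell <- collect(allRuns, "perWell")
  fc <- do.call(rbind, lapply(seq_along(trt), function(i) {
    b <- base[[baseIdx[i]]]$summary
    p <- trt[[i]]$summary
    data.frame(
      treatedWell = wellId(p), baselineWell = wellId(b),
      baselineMean = meanFociPerNucleus(b),
      treatedMean = meanFociPerNucleus(p),
      foldChange = foldChange(p, b)
    )
  }))

  utils::write.csv(perNucleus, file.path(outDir, "per_nucleus.csv"),
    row.names = FALSE
  )
  utils::write.csv(perField, file.path(outDir, "per_field.csv"),
    row.names = FALSE
  )
  utils::write.csv(perWell, file.path(outDir, "per_well.csv"),
    row.names = FALSE
  )
  utils::write.csv(fc, file.path(outDir, "fold_change.csv"),
    row.names = FALSE
  )
  logLines <- c(
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("baseline wells: %s", paste(baselineDirs, collapse = ", ")),
    sprintf("treated wells: %s", paste(treatedDirs, collapse = ", ")),
    sprintf(
      "segmentation: %s",
      paste(names(segCfg), unlist(segCfg), sep = "=", collapse = " ")
    ),
    sprintf(
      "foci: %s",
      paste(names(fociCfg), unlist(fociCfg), sep = "=", collapse = " ")
    ),
    sprintf(
      "filter: %s",
      paste(names(filter),
        vapply(filter, function(x) {
          if (is.null(x)) "auto" else format(x)
        }, character(1)),
        sep = "=", collapse = " "
      )
    )
  )
  writeLines(logLines, file.path(outDir, "pipeline.log"))
  invisible(list(
    perNucleus = perNucleus, perField = perField, perWell = perWell,
    foldChange = fc
  ))
}
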