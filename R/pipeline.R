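#' @include synthetic.R
NULL

#' Create an AnalysisConfig
#'
#' @param segments named list of \linkS4class{SegmentDef} (needs roles TM1,
#'   linker, H1, H4, TM2); default \code{\link{defaultSegments}()}
#' @param protomers a \linkS4class{ProtomerMap}
#' @param crickResidues residues reported by the Crick descriptor
#' @param crickReportRange residues averaged for rotation readout
#' @param contactPair intra-protomer CA contact pair
#' @param profileH1,profileH4 cross-protomer profile residue sets
#' @param linkerResidues linker residues classified by phi/psi
#' @param hbondAcceptors acceptor residues for H-bond classification
#' @param windowNs analysis window (last \code{windowNs} ns)
#' @param strideNs snapshot stride, ns
#' @param snapshotAlign residues aligning exported snapshots
#' @param coreAlign list of residue ranges for two-state superposition
#' @param seed seed for any resampling
#' @return an \linkS4class{AnalysisConfig}
#' @export
analysisConfig <- function(segments = defaultSegments(),
                           protomers = protomerMap("A", "B"),
                           crickResidues = c(47L, 50L),
                           crickReportRange = 43:55,
                           contactPair = c(50L, 133L),
                           profileH1 = 34:50, profileH4 = 133:147,
                           linkerResidues = 34:38,
                           hbondAcceptors = 47L,
                           windowNs = 200, strideNs = 10,
                           snapshotAlign = 45:55,
                           coreAlign = list(48:54, 122:130),
                           seed = 1L) {
  new("AnalysisConfig", segments = segments, protomers = protomers,
      crickResidues = as.integer(crickResidues),
      crickReportRange = as.integer(crickReportRange),
      contactPair = as.integer(contactPair),
      profileH1 = as.integer(profileH1), profileH4 = as.integer(profileH4),
      linkerResidues = as.integer(linkerResidues),
      hbondAcceptors = as.integer(hbondAcceptors),
      windowNs = windowNs, strideNs = strideNs,
      snapshotAlign = as.integer(snapshotAlign), coreAlign = coreAlign,
      seed = as.integer(seed))
}

.resolveSeg <- function(config, role, protomer) {
  s <- config@segments[[role]]
  if (is.null(s)) stop(sprintf("config has no segment with role %s", role))
  segmentDef(s@role, s@first, s@last, config@protomers@map[[protomer]])
}

.coreHelixSegments <- function(config) {
  out <- list()
  for (p in c("A", "B")) {
    for (role in c("H1", "H4")) out <- c(out, list(.resolveSeg(config, role, p)))
  }
  out
}

## bundle axis of a model under a config: pooled core helices, oriented
## N-to-C along protomer A's H1 (cytoplasm -> periplasm)
.modelBundleAxis <- function(model, config) {
  segs <- .coreHelixSegments(config)
  bundleAxis(lapply(segs, function(s) segmentAxis(model, s)))
}

#' Restrict a trajectory to its last T ns
#'
#' Keeps the frames with time strictly greater than t_end - T; when T
#' equals the full span the whole trajectory is returned.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param windowNs window length in ns (default 200)
#' @return a \linkS4class{Trajectory}
#' @export
windowLast <- function(traj, windowNs = 200) {
  tEnd <- max(traj@times)
  span <- tEnd - min(traj@times)
  if (windowNs > span + 1e-9)
    stop(sprintf(paste0("window of %g ns exceeds the trajectory span of %g ns; ",
                        "use windowNs <= %g or supply a longer trajectory"),
                 windowNs, span, span))
  keep <- if (abs(windowNs - span) <= 1e-9) rep(TRUE, length(traj@times))
  else traj@times > tEnd - windowNs + 1e-9
  newTrajectory(traj@frames[keep], traj@times[keep],
                provenance = traj@provenance)
}

.validateConfigAgainstTopology <- function(topo, config) {
  chA <- config@protomers@map[["A"]]; chB <- config@protomers@map[["B"]]
  df <- topo@residues
  have <- function(ch, r) any(df$chain == ch & df$resnum %in% r)
  need <- sort(unique(c(config@contactPair, config@profileH1,
                        config@profileH4, config@linkerResidues,
                        config@crickResidues)))
  for (ch in c(chA, chB)) {
    missing <- need[!need %in% df$resnum[df$chain == ch]]
    if (length(missing))
      stop(sprintf("config requests residue(s) %s absent from chain %s",
                   paste(missing, collapse = ", "), ch))
  }
  invisible(TRUE)
}

#' Evaluate the descriptor battery over a trajectory
#'
#' Per-frame, per-protomer evaluation of the configured descriptors: Crick
#' angles (via per-frame axis fits against the pooled core-helix bundle
#' axis), the intra-protomer contact distance, cross-protomer distance
#' profiles for the TM1/H1 and H4/TM2 sides, the TM1-TM2 piston shift
#' along the bundle axis, linker phi/psi state, and the backbone H-bond
#' class at the configured acceptor residues.  Isolated per-frame failures
#' are flagged missing and counted; a descriptor failing on more than half
#' of the frames aborts with a diagnostic.
#'
#' @param traj a \linkS4class{Trajectory} (already windowed if desired)
#' @param config an \linkS4class{AnalysisConfig}
#' @param outputDir optional directory for deterministic CSV outputs and a
#'   run log
#' @return list with elements crick (per-protomer
#'   \linkS4class{CrickSeries}), contact (per-protomer
#'   \linkS4class{DescriptorSeries}), piston (\linkS4class{DescriptorSeries}),
#'   profileH1/profileH4 (frames x residues matrices), linker (per-protomer
#'   frames x residues state matrices), hbond (per-protomer frames x
#'   acceptors class matrices), failureCounts, config
#' @export
runDescriptors <- function(traj, config, outputDir = NULL) {
  stopifnot(is(traj, "Trajectory"), is(config, "AnalysisConfig"))
  topo <- traj@frames[[1]]
  .validateConfigAgainstTopology(topo, config)
  nf <- length(traj@frames)
  labs <- c("A", "B")
  fail <- c(crick = 0L, contact = 0L, piston = 0L, profile = 0L,
            linker = 0L, hbond = 0L)

  crick <- crickSeries(traj, config@segments[["H1"]], config@crickResidues,
                       config@protomers, bundlePolicy = "bundle",
                       bundleSegments = NULL)
  fail["crick"] <- sum(vapply(crick, function(s) s@nMissing, integer(1)))

  contact <- lapply(labs, function(p) rep(NA_real_, nf))
  names(contact) <- labs
  piston <- rep(NA_real_, nf)
  prof1 <- matrix(NA_real_, nf, length(config@profileH1),
                  dimnames = list(NULL, config@profileH1))
  prof4 <- matrix(NA_real_, nf, length(config@profileH4),
                  dimnames = list(NULL, config@profileH4))
  linker <- lapply(labs, function(p)
    matrix("unknown", nf, length(config@linkerResidues),
           dimnames = list(NULL, config@linkerResidues)))
  names(linker) <- labs
  hbond <- lapply(labs, function(p)
    matrix(NA_character_, nf, length(config@hbondAcceptors),
           dimnames = list(NULL, config@hbondAcceptors)))
  names(hbond) <- labs

  for (f in seq_len(nf)) {
    m <- traj@frames[[f]]
    for (p in labs) {
      contact[[p]][f] <- tryCatch(
        intraProtomerDistance(m, config@protomers, p,
                              config@contactPair[1], config@contactPair[2]),
        error = function(e) { fail["contact"] <<- fail["contact"] + 1L; NA_real_ })
      st <- tryCatch(
        linkerState(m, config@protomers@map[[p]], config@linkerResidues)$states,
        error = function(e) { fail["linker"] <<- fail["linker"] + 1L; NULL })
      if (!is.null(st)) linker[[p]][f, ] <- st
      for (j in seq_along(config@hbondAcceptors)) {
        hbond[[p]][f, j] <- tryCatch(
          hbondClass(m, config@protomers@map[[p]], config@hbondAcceptors[j]),
          error = function(e) { fail["hbond"] <<- fail["hbond"] + 1L; NA_character_ })
      }
    }
    piston[f] <- tryCatch({
      z <- .modelBundleAxis(m, config)
      pistonShift(m, .resolveSeg(config, "TM1", "A"),
                  .resolveSeg(config, "TM2", "A"), z)
    }, error = function(e) { fail["piston"] <<- fail["piston"] + 1L; NA_real_ })
    p1 <- tryCatch(
      crossProtomerProfile(m, config@protomers, config@profileH1)@values,
      error = function(e) { fail["profile"] <<- fail["profile"] + 1L;
                            rep(NA_real_, ncol(prof1)) })
    prof1[f, ] <- p1
    p4 <- tryCatch(
      crossProtomerProfile(m, config@protomers, config@profileH4)@values,
      error = function(e) { fail["profile"] <<- fail["profile"] + 1L;
                            rep(NA_real_, ncol(prof4)) })
    prof4[f, ] <- p4
  }

  if (any(fail[c("contact", "piston")] > 0.5 * nf))
    stop(sprintf("descriptor failed on more than half of the frames: %s",
                 paste(names(fail)[fail > 0.5 * nf], collapse = ", ")))

  out <- list(
    crick = crick,
    contact = lapply(labs, function(p)
      descriptorSeries(sprintf("ca_dist_%d_%d", config@contactPair[1],
                               config@contactPair[2]),
                       "A", traj@times, contact[[p]], protomer = p)) |>
      stats::setNames(labs),
    piston = descriptorSeries("piston_tm1_tm2", "A", traj@times, piston),
    profileH1 = prof1, profileH4 = prof4, linker = linker, hbond = hbond,
    times = traj@times, failureCounts = fail, config = config)
  if (!is.null(outputDir)) .writeRunOutputs(out, outputDir)
  out
}

.writeRunOutputs <- function(res, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  cs <- do.call(rbind, lapply(res$crick, as.data.frame))
  utils::write.csv(cs, file.path(outputDir, "crick_angles.csv"),
                   row.names = FALSE)
  writeDescriptorTable(c(unname(res$contact), list(res$piston)),
                       file.path(outputDir, "contact_and_piston.csv"))
  for (side in c("profileH1", "profileH4")) {
    m <- res[[side]]
    df <- data.frame(frame_time_ns = res$times, m, check.names = FALSE)
    utils::write.csv(df, file.path(outputDir, paste0(side, ".csv")),
                     row.names = FALSE)
  }
  code <- c(helical = "H", disordered = "D", unknown = "U")
  lk <- do.call(rbind, lapply(names(res$linker), function(p) {
    m <- res$linker[[p]]
    data.frame(frame_time_ns = res$times, protomer = p,
               matrix(code[m], nrow(m), ncol(m),
                      dimnames = list(NULL, colnames(m))),
               check.names = FALSE)
  }))
  utils::write.csv(lk, file.path(outputDir, "linker_states.csv"),
                   row.names = FALSE)
  hb <- do.call(rbind, lapply(names(res$hbond), function(p) {
    data.frame(frame_time_ns = res$times, protomer = p, res$hbond[[p]],
               check.names = FALSE)
  }))
  utils::write.csv(hb, file.path(outputDir, "hbond_classes.csv"),
                   row.names = FALSE)
  log <- c("ccgeom descriptor run",
           sprintf("frames: %d (%.1f-%.1f ns)", length(res$times),
                   min(res$times), max(res$times)),
           sprintf("failure counts: %s",
                   paste(sprintf("%s=%d", names(res$failureCounts),
                                 res$failureCounts), collapse = " ")))
  writeLines(log, file.path(outputDir, "run_log.txt"))
  invisible(outputDir)
}

#' Overlay reference-structure values on descriptor summaries
#'
#' Evaluates the configured scalar descriptors (contact distances, piston,
#' Crick angles of the report residues) once on each labelled reference
#' model (e.g. crystallographic structures), for plotting next to
#' trajectory distributions.  References with incompatible numbering are
#' skipped with a warning.
#'
#' @param results a \code{\link{runDescriptors}} result
#' @param referenceModels named list of \linkS4class{StructureModel}
#' @return \code{results} with an \code{overlays} data.frame added
#' @export
overlayReference <- function(results, referenceModels) {
  config <- results$config
  rows <- list()
  for (nm in names(referenceModels)) {
    ref <- referenceModels[[nm]]
    ok <- tryCatch({ .validateConfigAgainstTopology(ref, config); TRUE },
                   error = function(e) {
                     warning(sprintf("reference %s skipped: %s", nm,
                                     conditionMessage(e)))
                     FALSE
                   })
    if (!ok) next
    for (p in c("A", "B")) {
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = sprintf("ca_dist_%d_%d", config@contactPair[1],
                             config@contactPair[2]),
        protomer = p, reference = nm,
        value = tryCatch(intraProtomerDistance(ref, config@protomers, p,
                                               config@contactPair[1],
                                               config@contactPair[2]),
                         error = function(e) NA_real_))
    }
    pv <- tryCatch({
      z <- .modelBundleAxis(ref, config)
      pistonShift(ref, .resolveSeg(config, "TM1", "A"),
                  .resolveSeg(config, "TM2", "A"), z)
    }, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(descriptor = "piston_tm1_tm2",
                                            protomer = "dimer",
                                            reference = nm, value = pv)
    for (p in c("A", "B")) {
      ca <- tryCatch({
        z <- .modelBundleAxis(ref, config)
        crickAngles(ref, .resolveSeg(config, "H1", p), z,
                    config@crickResidues)
      }, error = function(e) stats::setNames(rep(NA_real_,
                                                 length(config@crickResidues)),
                                             config@crickResidues))
      for (j in seq_along(ca)) {
        rows[[length(rows) + 1L]] <- data.frame(
          descriptor = sprintf("crick_%s", names(ca)[j]), protomer = p,
          reference = nm, value = unname(ca[j]))
      }
    }
  }
  results$overlays <- if (length(rows)) do.call(rbind, rows) else
    data.frame(descriptor = character(0), protomer = character(0),
               reference = character(0), value = numeric(0))
  results
}

#' Export superposed snapshots as a multi-model PDB
#'
#' Takes the last \code{windowNs} ns, picks the frame nearest each stride
#' point (each frame used at most once), superposes every snapshot onto
#' the first using the CA atoms of the alignment residue set on both
#' protomers, and writes a multi-model PDB.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param config an \linkS4class{AnalysisConfig}
#' @param path output PDB path
#' @return invisibly, a list with the path, snapshot count and frame times
#' @export
exportSnapshots <- function(traj, config, path) {
  w <- windowLast(traj, config@windowNs)
  targets <- seq(min(w@times), max(w@times), by = config@strideNs)
  idx <- unique(vapply(targets, function(t0)
    which.min(abs(w@times - t0)), integer(1)))
  frames <- w@frames[idx]
  aset <- do.call(rbind, lapply(config@protomers@map, function(ch)
    data.frame(chain = ch, resnum = config@snapshotAlign)))
  aligned <- tryCatch({
    lapply(seq_along(frames), function(k) {
      if (k == 1L) return(frames[[k]])
      applyTransform(frames[[k]],
                     kabschSuperpose(frames[[1]], frames[[k]], aset))
    })
  }, error = function(e) {
    warning(sprintf("alignment set unavailable (%s); exporting unaligned",
                    conditionMessage(e)))
    frames
  })
  writeTrajectory(newTrajectory(aligned, w@times[idx]), path)
  invisible(list(path = path, nSnapshots = length(idx),
                 times = w@times[idx]))
}

.axialDisplacement <- function(ref, mobile, config, movingRole, partnerRole) {
  pset <- do.call(rbind, lapply(c("A", "B"), function(p) {
    s <- .resolveSeg(config, partnerRole, p)
    data.frame(chain = s@chain, resnum = seq(s@first, s@last))
  }))
  tr <- kabschSuperpose(ref, mobile, pset)
  mob <- applyTransform(mobile, tr)
  segs <- .coreHelixSegments(config)
  axes <- c(lapply(segs, function(s) segmentAxis(ref, s)),
            lapply(segs, function(s) segmentAxis(mob, s)))
  z <- bundleAxis(axes)@direction
  rows <- list()
  for (p in c("A", "B")) {
    s <- .resolveSeg(config, movingRole, p)
    for (r in seq(s@first, s@last)) {
      a <- .atomCoord(ref, s@chain, r, "CA")
      b <- .atomCoord(mob, s@chain, r, "CA")
      rows[[length(rows) + 1L]] <- data.frame(
        pair = sprintf("%s_vs_%s", movingRole, partnerRole), protomer = p,
        resnum = r, dz = sum((b - a) * z))
    }
  }
  do.call(rbind, rows)
}

#' Compare two conformational states of a dimer
#'
#' After superposing the second structure onto the first over the core
#' alignment set, reports: the per-residue circular Crick-angle change
#' over the membrane-proximal H1 report range, the cross-protomer distance
#' changes for both profile sets, the per-residue axial displacement of
#' TM1 measured relative to TM2 (and of H1 relative to H4) along the
#' bundle axis, the linker phi/psi classification of each structure, and
#' max/mean axial displacements per segment pair.  Swapping the arguments
#' flips the sign of every displacement field.
#'
#' @param bound,free dimeric \linkS4class{StructureModel}s with compatible
#'   numbering (the names reflect the canonical use; any two states work)
#' @param config an \linkS4class{AnalysisConfig}
#' @return a \linkS4class{TwoStateComparison}
#' @export
compareTwoStates <- function(bound, free, config = analysisConfig()) {
  for (m in list(bound, free)) {
    if (length(unique(m@residues$chain)) != 2L)
      stop("compareTwoStates requires dimeric (two-chain) models")
  }
  core <- do.call(rbind, lapply(config@protomers@map, function(ch)
    do.call(rbind, lapply(config@coreAlign, function(r)
      data.frame(chain = ch, resnum = r)))))
  free <- applyTransform(free, kabschSuperpose(bound, free, core))

  crick <- do.call(rbind, lapply(c("A", "B"), function(p) {
    segB <- .resolveSeg(config, "H1", p)
    zB <- .modelBundleAxis(bound, config)
    zF <- .modelBundleAxis(free, config)
    cb <- crickAngles(bound, segB, zB, config@crickReportRange)
    cf <- crickAngles(free, segB, zF, config@crickReportRange)
    data.frame(protomer = p, resnum = config@crickReportRange,
               crickChange = circularDiff(cf, cb))
  }))

  prof <- do.call(rbind, lapply(list(c("H1", "profileH1"), c("H4", "profileH4")),
                                function(side) {
    rs <- slot(config, side[2])
    pb <- crossProtomerProfile(bound, config@protomers, rs)@values
    pf <- crossProtomerProfile(free, config@protomers, rs)@values
    data.frame(side = side[1], resnum = rs, change = pf - pb)
  }))

  ax <- rbind(.axialDisplacement(bound, free, config, "TM1", "TM2"),
              .axialDisplacement(bound, free, config, "H1", "H4"))

  lk <- do.call(rbind, lapply(list(c("bound", "A"), c("bound", "B"),
                                   c("free", "A"), c("free", "B")),
                              function(sp) {
    m <- if (sp[1] == "bound") bound else free
    data.frame(structure = sp[1], protomer = sp[2],
               state = linkerState(m, config@protomers@map[[sp[2]]],
                                   config@linkerResidues)$call)
  }))

  sm <- do.call(rbind, lapply(split(ax, ax$pair), function(d)
    data.frame(pair = d$pair[1],
               maxAbsDz = max(abs(d$dz)), meanDz = mean(d$dz))))
  rownames(sm) <- NULL

  new("TwoStateComparison", crickChange = crick, profileChange = prof,
      axialDisplacement = ax, linkerStates = lk, summary = sm)
}
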