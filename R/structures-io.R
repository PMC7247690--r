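#' @include accessors.R
NULL

# PDB input/output goes through bio3d; this file only adapts between the
# per-atom bio3d table and the per-residue backbone layout used here, and
# frames/splits MODEL blocks for multi-model files.

.bio3dToResidues <- function(pdb) {
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% .ATOMS, , drop = FALSE]
  if (nrow(at) == 0L) stop("no backbone ATOM records found", call. = FALSE)
  # alternate locations: keep the highest-occupancy conformer
  if (any(!is.na(at$alt) & at$alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  at$chain[is.na(at$chain)] <- "A"
  rk <- paste(at$chain, at$resno)
  ures <- !duplicated(rk)
  df <- data.frame(chain = at$chain[ures], resnum = at$resno[ures],
                   resname = at$resid[ures], stringsAsFactors = FALSE)
  for (a in .ATOMS) for (cc in c("x", "y", "z")) df[[paste0(a, cc)]] <- NA_real_
  rows <- match(rk, rk[ures])
  for (i in seq_len(nrow(at))) {
    df[rows[i], .coordCols(at$elety[i])] <- c(at$x[i], at$y[i], at$z[i])
  }
  if (all(is.na(df$CAx))) stop("model contains no CA atoms", call. = FALSE)
  if (any(is.na(df$CAx)))
    stop(sprintf("residue(s) without CA: %s",
                 paste(df$resnum[is.na(df$CAx)], collapse = ", ")), call. = FALSE)
  df
}

#' Read a structure from a PDB file
#'
#' Reads backbone (N, CA, C, O) ATOM records; residues keep their author
#' numbering.  Alternate locations collapse to the highest-occupancy
#' conformer; missing non-CA atoms are kept as NA and flagged downstream.
#' For a multi-model file only the first MODEL is read (use
#' \code{\link{readTrajectory}} for all frames).
#'
#' @param path PDB file path.
#' @param label model label (default: file name).
#' @return a \linkS4class{StructureModel}
#' @export
readStructure <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop(sprintf("cannot parse '%s' as PDB: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  structureModel(.bio3dToResidues(pdb), label = label)
}

.modelToBio3dVectors <- function(model) {
  df <- model@residues
  out <- list(xyz = numeric(0), resno = integer(0), chain = character(0),
              resid = character(0), elety = character(0))
  for (i in seq_len(nrow(df))) {
    for (a in .ATOMS) {
      co <- as.numeric(df[i, .coordCols(a)])
      if (all(is.finite(co))) {
        out$xyz <- c(out$xyz, co)
        out$resno <- c(out$resno, df$resnum[i])
        out$chain <- c(out$chain, df$chain[i])
        out$resid <- c(out$resid, df$resname[i])
        out$elety <- c(out$elety, a)
      }
    }
  }
  out
}

#' Write a structure to a PDB file
#'
#' @param model a \linkS4class{StructureModel}
#' @param path output path.
#' @return invisibly, the path
#' @export
writeStructure <- function(model, path) {
  v <- .modelToBio3dVectors(model)
  bio3d::write.pdb(file = path, xyz = v$xyz, resno = v$resno, chain = v$chain,
                   resid = v$resid, elety = v$elety)
  invisible(path)
}

.pdbAtomLines <- function(model) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeStructure(model, tf)
  ln <- readLines(tf)
  ln[grepl("^ATOM|^TER", ln)]
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a \linkS4class{Trajectory}
#' @param path output path.
#' @return invisibly, the path
#' @export
writeTrajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj@frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(.pdbAtomLines(traj@frames[[k]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.splitModels <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("multi-model PDB has unbalanced MODEL/ENDMDL records", call. = FALSE)
  mapply(function(s, e) lines[(s + 1):(e - 1)], starts, ends, SIMPLIFY = FALSE)
}

.parseModelLines <- function(lines, label) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(lines, "END"), tf)
  readStructure(tf, label = label)
}

## conform a frame to the topology's residue ordering; atoms are matched by
## (chain, resnum, atom name), so permuted records are accepted
.conformToTopology <- function(frame, topo, k) {
  ft <- frame@residues; tt <- topo@residues
  idx <- match(paste(tt$chain, tt$resnum), paste(ft$chain, ft$resnum))
  if (anyNA(idx) || nrow(ft) != nrow(tt))
    stop(sprintf("frame %d does not match topology (residue set differs)", k),
         call. = FALSE)
  ft <- ft[idx, , drop = FALSE]
  rownames(ft) <- NULL
  if (!identical(is.na(ft[, .ALLCOORDS]), is.na(tt[, .ALLCOORDS])))
    stop(sprintf("frame %d does not match topology (atom set differs)", k),
         call. = FALSE)
  if (!identical(ft$resname, tt$resname))
    stop(sprintf("frame %d does not match topology (residue names differ)", k),
         call. = FALSE)
  structureModel(ft, label = frame@label)
}

#' Read a trajectory
#'
#' Reads a multi-model PDB as an ordered set of frames sharing one topology.
#' A separate topology file may be given; otherwise the first model serves
#' as topology.  Atom records may be permuted between models (they are
#' matched by chain, residue number and atom name); any difference in the
#' residue or atom sets is a topology error.
#'
#' @param coordsPath multi-model PDB with the frames.
#' @param frameDtNs frame spacing in ns; frame times are
#'   \code{(0:(n-1)) * frameDtNs}.
#' @param topologyPath optional single-model PDB defining the topology.
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectory <- function(coordsPath, frameDtNs = 1, topologyPath = NULL) {
  if (!file.exists(coordsPath)) stop(sprintf("file not found: %s", coordsPath))
  chunks <- .splitModels(readLines(coordsPath))
  frames <- lapply(seq_along(chunks), function(k)
    .parseModelLines(chunks[[k]], sprintf("%s#%d", basename(coordsPath), k)))
  topo <- if (is.null(topologyPath)) frames[[1]] else readStructure(topologyPath)
  frames <- lapply(seq_along(frames), function(k)
    .conformToTopology(frames[[k]], topo, k))
  newTrajectory(frames, (seq_along(frames) - 1) * frameDtNs)
}

# ---- descriptor tables ----------------------------------------------------

#' Write a collection of descriptor series as a CSV table
#'
#' All series must share one index (frame times or residue numbers); the
#' header carries name, units and protomer as \code{name.protomer [units]}.
#' NA (flagged) values are written as empty cells.  Values round-trip at
#' full precision through \code{\link{readDescriptorTable}}.
#'
#' @param seriesList list of \linkS4class{DescriptorSeries}
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeDescriptorTable <- function(seriesList, path) {
  if (length(seriesList) == 0L) {
    writeLines("index", path)
    return(invisible(path))
  }
  stopifnot(all(vapply(seriesList, is, logical(1), "DescriptorSeries")))
  idx <- seriesList[[1]]@index
  itype <- seriesList[[1]]@indexType
  for (s in seriesList) {
    if (!identical(s@index, idx) || !identical(s@indexType, itype))
      stop("descriptor series do not share one index", call. = FALSE)
  }
  df <- data.frame(index = idx)
  names(df) <- itype
  for (s in seriesList) {
    df[[sprintf("%s.%s [%s]", s@name, s@protomer, s@units)]] <- s@values
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a descriptor table written by \code{\link{writeDescriptorTable}}
#'
#' @param path CSV path
#' @return list of \linkS4class{DescriptorSeries}
#' @export
readDescriptorTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) return(list())
  itype <- names(df)[1]
  out <- list()
  for (j in 2:ncol(df)) {
    nm <- names(df)[j]
    m <- regmatches(nm, regexec("^(.*)\\.([^. ]+) \\[(.*)\\]$", nm))[[1]]
    out[[nm]] <- descriptorSeries(name = m[2], units = m[4],
                                  index = as.numeric(df[[1]]),
                                  values = as.numeric(df[[j]]),
                                  indexType = itype, protomer = m[3])
  }
  out
}

# ---- segment configuration files -----------------------------------------

#' Read a segment-definition config
#'
#' Flat whitespace-delimited text, one segment per line:
#' \code{role chain first last} (chain "-" for unresolved).  Lines starting
#' with \code{#} are comments.
#'
#' @param path config path
#' @return named list of \linkS4class{SegmentDef}
#' @export
readSegmentConfig <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  out <- list()
  for (l in ln) {
    f <- strsplit(l, "[[:space:]]+")[[1]]
    if (length(f) != 4L)
      stop(sprintf("bad segment line (need 'role chain first last'): %s", l))
    ch <- if (f[2] == "-") NA_character_ else f[2]
    out[[f[1]]] <- segmentDef(f[1], as.integer(f[3]), as.integer(f[4]), ch)
  }
  out
}

#' Write a segment-definition config
#'
#' @param segments named list of \linkS4class{SegmentDef}
#' @param path output path
#' @return invisibly, the path
#' @export
writeSegmentConfig <- function(segments, path) {
  ln <- vapply(segments, function(s) {
    sprintf("%s %s %d %d", s@role,
            if (is.na(s@chain)) "-" else s@chain, s@first, s@last)
  }, character(1))
  writeLines(ln, path)
  invisible(path)
}
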