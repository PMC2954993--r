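# Frame-to-frame tracking by optimal assignment, with an optional
# spectral-fingerprint cost term and conflict (crossing) resolution.

# Minimum-cost square assignment; exhaustive over permutations in
# lexicographic order for n <= 9 (first strict minimum, so ties resolve
# to the lexicographically smallest assignment = lowest id), greedy
# beyond. Inf marks disallowed pairs.
.solveAssignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  if (n <= 9L) {
    perms <- .permutations(n)
    best <- NULL
    bestCost <- Inf
    idx <- seq_len(n)
    for (r in seq_len(nrow(perms))) {
      cc <- sum(cost[cbind(idx, perms[r, ])])
      if (is.finite(cc) && cc < bestCost) {
        bestCost <- cc
        best <- perms[r, ]
      }
    }
    if (is.null(best)) stop("no feasible assignment")
    return(best)
  }
  # greedy fallback for large frames
  assign <- integer(n)
  free <- rep(TRUE, n)
  ord <- order(cost)
  for (k in ord) {
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (assign[i] == 0L && free[j] && is.finite(cost[i, j])) {
      assign[i] <- j
      free[j] <- FALSE
    }
  }
  if (any(assign == 0L)) {
    left <- which(assign == 0L)
    assign[left] <- which(free)[seq_along(left)]
  }
  assign
}

.fracCols <- function(dets) grep("^I_", names(dets), value = TRUE)

# Core tracker. dets: data.frame(frame, x, y, I_* ...). Returns TrackSet.
.trackEngine <- function(dets, w, gate, conflictRadius, ambiguityTol,
                         resolveConflicts, mode) {
  if (w < 0) stop("'w' (fingerprint cost weight) must be nonnegative")
  icols <- .fracCols(dets)
  if (!length(icols)) stop("detections must carry I_<fluorophore> columns")
  frames <- sort(unique(dets$frame))
  if (length(frames) < 2L) stop("at least 2 frames are required for tracking")
  itot <- rowSums(dets[, icols, drop = FALSE])
  fr <- as.matrix(dets[, icols, drop = FALSE]) / ifelse(itot > 0, itot, 1)

  skipCost <- gate + 2 * w + 1
  nextId <- 1L
  trkId <- integer(0)       # per active track
  trkPos <- matrix(numeric(0), 0L, 2L)
  trkFrac <- matrix(numeric(0), 0L, length(icols))
  outRows <- vector("list", length(frames))

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- which(dets$frame == f)
    nc <- length(cur)
    nr <- length(trkId)
    if (nr == 0L || nc == 0L) {
      ids <- if (nc) seq.int(nextId, length.out = nc) else integer(0)
      nextId <- nextId + nc
    } else {
      spat <- .crossDist(trkPos, as.matrix(dets[cur, c("x", "y")]))
      fdist <- matrix(0, nr, nc)
      for (k in seq_len(ncol(trkFrac)))
        fdist <- fdist + abs(outer(trkFrac[, k], fr[cur, k], "-"))
      cost <- spat + w * fdist
      cost[spat > gate] <- Inf
      if (nr == nc && all(is.finite(cost))) {
        sol <- .solveAssignment(cost)
        ids <- integer(nc)
        ids[sol] <- trkId
      } else {
        size <- nr + nc
        M <- matrix(Inf, size, size)
        M[seq_len(nr), seq_len(nc)] <- cost
        for (i in seq_len(nr)) M[i, nc + i] <- skipCost
        for (j in seq_len(nc)) M[nr + j, j] <- skipCost
        M[nr + seq_len(nc), nc + seq_len(nr)] <- 0
        sol <- .solveAssignment(M)
        ids <- integer(nc)
        for (i in seq_len(nr)) {
          j <- sol[i]
          if (j <= nc) ids[j] <- trkId[i]
        }
        newDet <- which(ids == 0L)
        if (length(newDet)) {
          ids[newDet] <- seq.int(nextId, length.out = length(newDet))
          nextId <- nextId + length(newDet)
        }
      }
    }
    if (nc) {
      outRows[[fi]] <- data.frame(frame = f, track_id = ids,
                                  x = dets$x[cur], y = dets$y[cur],
                                  det_row = cur)
      # active set for next frame = tracks observed in this frame
      trkId <- ids
      trkPos <- as.matrix(dets[cur, c("x", "y")])
      trkFrac <- fr[cur, , drop = FALSE]
    } else {
      trkId <- integer(0)
      trkPos <- matrix(numeric(0), 0L, 2L)
      trkFrac <- matrix(numeric(0), 0L, length(icols))
    }
  }
  tr <- do.call(rbind, outRows)
  for (k in seq_along(icols))
    tr[[sub("^I_", "frac_", icols[k])]] <- fr[tr$det_row, k]
  tr <- tr[order(tr$frame, tr$track_id), ]
  rownames(tr) <- NULL

  events <- .findConflicts(tr, conflictRadius)
  resolved <- 0L
  ambiguous <- 0L
  if (resolveConflicts && nrow(events)) {
    fcols <- grep("^frac_", names(tr), value = TRUE)
    for (e in seq_len(nrow(events))) {
      ids <- as.integer(strsplit(events$track_ids[e], ",")[[1L]])
      pre <- .meanFingerprint(tr, ids, fcols, tr$frame < events$f_start[e])
      post <- .meanFingerprint(tr, ids, fcols, tr$frame > events$f_end[e])
      have <- !is.na(pre[, 1L]) & !is.na(post[, 1L])
      if (sum(have) < 2L) next
      hIds <- ids[have]
      preH <- pre[have, , drop = FALSE]
      postH <- post[have, , drop = FALSE]
      pd <- as.matrix(stats::dist(preH, method = "manhattan"))
      if (max(pd[upper.tri(pd)]) < ambiguityTol) {
        ambiguous <- ambiguous + 1L
        next
      }
      perms <- .permutations(length(hIds))
      costs <- apply(perms, 1L, function(p)
        sum(abs(preH - postH[p, , drop = FALSE])))
      p <- perms[which.min(costs), ]
      if (!all(p == seq_along(hIds))) {
        sel <- tr$frame > events$f_end[e] & tr$track_id %in% hIds
        old <- tr$track_id[sel]
        tr$track_id[sel] <- hIds[match(old, hIds[p])]
      }
      resolved <- resolved + 1L
    }
    tr <- tr[order(tr$frame, tr$track_id), ]
    rownames(tr) <- NULL
  }
  report <- list(mode = mode, weight = w, gate = gate,
                 conflict_radius = conflictRadius,
                 conflicts = nrow(events),
                 resolved_by_spectrum = resolved,
                 ambiguous = ambiguous,
                 conflict_events = events)
  new("TrackSet", tracks = tr, report = report)
}

# Conflict events: maximal runs of consecutive frames in which a group of
# >= 2 tracks sits pairwise-connected within the conflict radius.
.findConflicts <- function(tr, conflictRadius) {
  frames <- sort(unique(tr$frame))
  open <- list()   # each: list(ids, f_start, f_end)
  done <- list()
  for (f in frames) {
    rows <- tr[tr$frame == f, , drop = FALSE]
    groups <- list()
    if (nrow(rows) >= 2L) {
      d <- .crossDist(as.matrix(rows[, c("x", "y")]),
                      as.matrix(rows[, c("x", "y")]))
      adj <- d <= conflictRadius
      adj[!upper.tri(adj)] <- FALSE
      comp <- .unionFind(nrow(rows), which(adj, arr.ind = TRUE))
      for (k in seq_len(max(comp))) {
        ids <- sort(rows$track_id[comp == k])
        if (length(ids) >= 2L) groups <- c(groups, list(ids))
      }
    }
    still <- rep(FALSE, length(open))
    for (g in groups) {
      merged <- FALSE
      for (o in seq_along(open)) {
        if (open[[o]]$f_end == f - 1L &&
            length(intersect(open[[o]]$ids, g)) >= 2L) {
          open[[o]]$ids <- sort(union(open[[o]]$ids, g))
          open[[o]]$f_end <- f
          still[o] <- TRUE
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        open <- c(open, list(list(ids = g, f_start = f, f_end = f)))
        still <- c(still, TRUE)
      }
    }
    done <- c(done, open[!still])
    open <- open[still]
  }
  done <- c(done, open)
  if (!length(done))
    return(data.frame(f_start = integer(0), f_end = integer(0),
                      n_tracks = integer(0), track_ids = character(0)))
  data.frame(
    f_start = vapply(done, `[[`, numeric(1), "f_start"),
    f_end = vapply(done, `[[`, numeric(1), "f_end"),
    n_tracks = vapply(done, function(x) length(x$ids), integer(1)),
    track_ids = vapply(done, function(x) paste(x$ids, collapse = ","),
                       character(1))
  )
}

# Mean fraction vector per track id over the selected frames (up to the
# 5 frames nearest the conflict); NA row when a track has no such frames.
.meanFingerprint <- function(tr, ids, fcols, selector) {
  out <- matrix(NA_real_, length(ids), length(fcols))
  for (i in seq_along(ids)) {
    rows <- tr[selector & tr$track_id == ids[i], , drop = FALSE]
    if (!nrow(rows)) next
    rows <- rows[order(rows$frame), , drop = FALSE]
    take <- if (nrow(rows) > 5L) tail(seq_len(nrow(rows)), 5L)
            else seq_len(nrow(rows))
    out[i, ] <- colMeans(as.matrix(rows[take, fcols, drop = FALSE]))
  }
  out
}

#' Spectrum-blind nearest-neighbor tracking
#'
#' Frame-to-frame minimum-cost assignment on spatial displacement alone,
#' gated at a maximum displacement per frame; ties broken toward the
#' lowest track id. A cell disappearing mid-movie terminates its track
#' rather than jumping beyond the gate. This is the baseline that must
#' guess at trajectory crossings.
#'
#' @param dets data.frame of detections with columns frame, x, y and one
#'   \code{I_<fluorophore>} column per fluorophore (see
#'   \code{\link{truthDetections}} and \code{\link{detectMovie}}).
#' @param gate maximum displacement per frame in micrometres (default 30,
#'   three nuclear diameters).
#' @param conflictRadius distance below which co-located tracks are
#'   recorded as a conflict event (default 10, one nuclear diameter).
#' @return a \linkS4class{TrackSet}.
#' @export
nearestNeighborTrack <- function(dets, gate = 30, conflictRadius = 10) {
  .trackEngine(dets, w = 0, gate = gate, conflictRadius = conflictRadius,
               ambiguityTol = 0.1, resolveConflicts = FALSE, mode = "blind")
}

#' Spectral-fingerprint tracking with crossing resolution
#'
#' Same assignment engine as \code{\link{nearestNeighborTrack}} but with
#' combined cost: spatial displacement plus \code{w} times the L1
#' fingerprint distance. At every conflict event (tracks co-located
#' within the conflict radius) the identities after separation are
#' re-assigned to minimize the total fingerprint distance to the
#' pre-conflict fingerprints -- the automated form of stepping backward
#' in the time-lapse to read each cell's spectral identity, then stepping
#' forward to re-acquire it. Conflicts whose pre-conflict fingerprints
#' are all within the ambiguity tolerance are flagged as ambiguous and
#' left to the positional assignment, not guessed.
#'
#' With \code{w = 0} the fingerprint term and the conflict re-assignment
#' are disabled and the result is identical to the blind tracker.
#'
#' @inheritParams nearestNeighborTrack
#' @param w fingerprint cost weight in micrometres per unit L1 distance;
#'   the default 10 makes a fully distinct fingerprint (L1 = 2) cost as
#'   much as a two-diameter displacement.
#' @param ambiguityTol L1 distance below which fingerprints are
#'   considered indistinguishable (default 0.1).
#' @return a \linkS4class{TrackSet}.
#' @export
spectralTrack <- function(dets, w = 10, gate = 30, conflictRadius = 10,
                          ambiguityTol = 0.1) {
  if (w < 0) stop("'w' must be nonnegative")
  .trackEngine(dets, w = w, gate = gate, conflictRadius = conflictRadius,
               ambiguityTol = ambiguityTol, resolveConflicts = w > 0,
               mode = if (w > 0) "spectral" else "blind")
}

#' Count identity switches of a tracking result against ground truth
#'
#' Each reported track position is matched to the nearest ground-truth
#' cell in its frame; an identity switch is a frame-to-frame change of
#' the matched truth label within one track. A change from a parent to
#' one of its daughters (per the truth lineage) is a division, not a
#' switch.
#'
#' @param trackset a \linkS4class{TrackSet}.
#' @param truth ground-truth data.frame as in
#'   \code{\link{movieTruth}} (columns frame, cell_id, x, y, parent_id).
#' @return list with \code{switches}, \code{n_tracks}, \code{labels}
#'   (data.frame frame, track_id, truth_id) and the tracking report's
#'   conflict counts.
#' @export
evaluateTracking <- function(trackset, truth) {
  stopifnot(is(trackset, "TrackSet"))
  tr <- tracks(trackset)
  if (!all(tr$frame %in% truth$frame))
    stop("track frames extend beyond the ground truth's frame range")
  parentOf <- function(id) {
    p <- truth$parent_id[match(id, truth$cell_id)]
    ifelse(is.na(p), -1L, p)
  }
  # Per track, match each position to the nearest truth cell of its
  # frame; exact distance ties (cells co-located at optical resolution)
  # stick with the track's previous label rather than inventing a change.
  lab <- integer(nrow(tr))
  switches <- 0L
  for (id in unique(tr$track_id)) {
    sel <- which(tr$track_id == id)
    sel <- sel[order(tr$frame[sel])]
    prev <- NA_integer_
    for (i in sel) {
      tu <- truth[truth$frame == tr$frame[i], , drop = FALSE]
      d <- sqrt((tu$x - tr$x[i])^2 + (tu$y - tr$y[i])^2)
      cand <- tu$cell_id[d <= min(d) + 1e-9]
      lab[i] <- if (!is.na(prev) && prev %in% cand) prev else cand[1L]
      prev <- lab[i]
    }
    l <- lab[sel]
    if (length(l) >= 2L) {
      chg <- which(l[-1L] != l[-length(l)])
      for (c in chg) {
        if (parentOf(l[c + 1L]) != l[c]) switches <- switches + 1L
      }
    }
  }
  rep <- trackingReport(trackset)
  list(switches = switches,
       n_tracks = length(unique(tr$track_id)),
       labels = data.frame(frame = tr$frame, track_id = tr$track_id,
                           truth_id = lab),
       conflicts = rep$conflicts,
       resolved_by_spectrum = rep$resolved_by_spectrum,
       ambiguous = rep$ambiguous)
}
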