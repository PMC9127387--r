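# Detection-free multi-target management: independent tracker instances
# initialized manually (no automatic births), stepped strictly online, with
# inter-target geometry reported afterwards in the rotated spine coordinate
# frame. No data association is performed — targets never exchange identity.

#' Create an empty target registry
#'
#' @return A `target_registry`.
#' @export
target_registry <- function() {
  structure(list(entries = list()), class = "target_registry")
}

#' Register a target for multi-target tracking
#'
#' Every target is initialized manually (detection-free tracking): an id, a
#' kind, the frame at which tracking starts, and the initial box. The
#' tracker itself is created lazily when the run reaches the start frame.
#'
#' @param reg A [target_registry()].
#' @param id Unique target label.
#' @param kind `"organ"` (combined correlation-filter tracker) or `"bolus"`
#'   (discrete-point tracker).
#' @param start_frame 1-based frame index at which tracking begins.
#' @param box Initial [bbox()] on the start frame.
#' @return Updated registry.
#' @export
register_target <- function(reg, id, kind = c("organ", "bolus"),
                            start_frame = 1, box) {
  kind <- match.arg(kind)
  ids <- vapply(reg$entries, `[[`, character(1), "id")
  if (id %in% ids) stop("duplicate target id: ", id)
  reg$entries[[length(reg$entries) + 1]] <-
    list(id = id, kind = kind, start_frame = as.integer(start_frame),
         box = box)
  reg
}

# one independent tracker run over frames start..n; per-target RNG streams
# keep targets independent of one another
run_single_target <- function(entry, seq, cfg, seed) {
  n <- length(seq$frames)
  s0 <- entry$start_frame
  sub <- video_sequence(seq$frames[s0:n], seq$frame_rate, seq$source_id)
  tseed <- derive_seed(seed, paste0("target-", entry$id))
  r <- if (entry$kind == "bolus") {
    track_bolus(sub, entry$box, cfg, tseed)
  } else {
    # an occluded organ is NOT lost: the combined tracker freezes its
    # templates and coasts, so only bolus targets (empty mask) can be lost
    track_organ(sub, entry$box, cfg)
  }
  lost <- if (!is.null(r$lost)) r$lost else logical(n - s0 + 1)
  # terminate after lost_patience consecutive lost frames; never revived
  term_at <- NA_integer_
  run <- 0L
  for (i in seq_along(lost)) {
    run <- if (lost[i]) run + 1L else 0L
    if (run > cfg$lost_patience) { term_at <- i; break }
  }
  keep <- if (is.na(term_at)) seq_along(lost) else seq_len(term_at)
  trajectory(entry$id, s0 - 1 + keep, r$trajectory$boxes[keep],
             r$trajectory$centroids[keep, , drop = FALSE],
             r$trajectory$scores[keep])
}

#' Run all registered targets online over a sequence
#'
#' Each tracker is stepped independently, strictly in frame order with no
#' lookahead; one target losing its object never affects another. After
#' tracking, pairwise relations (center distance in the rotated spine
#' coordinate frame, and box IoU) are computed per frame from the stored
#' trajectories.
#'
#' @param reg A [target_registry()] with at least one entry.
#' @param seq [video_sequence()].
#' @param rot A [rotation_spec()] defining the spine coordinate frame (use
#'   angle 0 for raw image coordinates).
#' @param cfg [run_config()].
#' @param seed Integer seed.
#' @return List with `trajectories` (named list) and `relations`
#'   (data.frame: `frame`, `id_a`, `id_b`, `distance` px in rotated
#'   coordinates, `overlap` box IoU). Targets terminated after more than
#'   `lost_patience` consecutive lost frames have shortened trajectories.
#' @export
run_online <- function(reg, seq, rot = rotation_spec(c(0, 0), 0),
                       cfg = run_config(), seed = 1) {
  if (length(reg$entries) == 0) stop("no targets registered")
  trajs <- lapply(reg$entries, run_single_target, seq = seq, cfg = cfg,
                  seed = seed)
  names(trajs) <- vapply(reg$entries, `[[`, character(1), "id")
  M <- rotation_matrix(rot$center, rot$angle)
  rel <- list()
  ids <- names(trajs)
  if (length(ids) >= 2) {
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        ta <- trajs[[a]]; tb <- trajs[[b]]
        common <- intersect(ta$frames, tb$frames)
        if (length(common) == 0) next
        ia <- match(common, ta$frames); ib <- match(common, tb$frames)
        ca <- transform_points(M, ta$centroids[ia, , drop = FALSE])
        cb <- transform_points(M, tb$centroids[ib, , drop = FALSE])
        dist <- sqrt(rowSums((ca - cb)^2))
        ov <- vapply(seq_along(common), function(i)
          bbox_iou(ta$boxes[[ia[i]]], tb$boxes[[ib[i]]]), numeric(1))
        rel[[length(rel) + 1]] <- data.frame(
          frame = common, id_a = ids[a], id_b = ids[b],
          distance = dist, overlap = ov)
      }
    }
  }
  relations <- if (length(rel)) do.call(rbind, rel) else
    data.frame(frame = integer(), id_a = character(), id_b = character(),
               distance = numeric(), overlap = numeric())
  list(trajectories = trajs, relations = relations)
}
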