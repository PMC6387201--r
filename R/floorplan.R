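#' Construct a floorplan of labelled rectangular rooms
#'
#' A floorplan is the geometric substrate of the simulator: a set of labelled
#' axis-aligned rectangular rooms, plus explicit wall segments used by the
#' radio propagation model to add per-wall attenuation. Rooms are closed on
#' their lower/left edges and open on their upper/right edges, so every
#' interior point of the house maps to at most one room.
#'
#' @param rooms data.frame with columns `room`, `xmin`, `xmax`, `ymin`, `ymax`
#'   (metres, origin at the lower-left corner of the house).
#' @param walls data.frame with columns `x0`, `y0`, `x1`, `y1`: line segments
#'   that attenuate the radio signal. Room boundaries without a wall (open
#'   archways) are simply omitted.
#' @return An object of class `floorplan`.
#' @examples
#' fp <- default_floorplan()
#' room_at(fp, 1, 1)
#' @export
floorplan <- function(rooms, walls = NULL) {
  stopifnot(is.data.frame(rooms),
            all(c("room", "xmin", "xmax", "ymin", "ymax") %in% names(rooms)))
  rooms$room <- as.character(rooms$room)
  if (anyDuplicated(rooms$room))
    stop("room labels must be unique")
  if (any(rooms$xmax <= rooms$xmin) || any(rooms$ymax <= rooms$ymin))
    stop("degenerate room rectangle")
  # pairwise overlap check (open upper/right edges, so touching is fine)
  n <- nrow(rooms)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (rooms$xmin[i] < rooms$xmax[j] && rooms$xmin[j] < rooms$xmax[i] &&
          rooms$ymin[i] < rooms$ymax[j] && rooms$ymin[j] < rooms$ymax[i])
        stop(sprintf("rooms '%s' and '%s' overlap", rooms$room[i], rooms$room[j]))
    }
  }
  if (is.null(walls))
    walls <- data.frame(x0 = numeric(0), y0 = numeric(0),
                        x1 = numeric(0), y1 = numeric(0))
  structure(list(rooms = rooms, walls = walls,
                 bounds = c(xmin = min(rooms$xmin), xmax = max(rooms$xmax),
                            ymin = min(rooms$ymin), ymax = max(rooms$ymax))),
            class = "floorplan")
}

#' @export
print.floorplan <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("floorplan: %d rooms, %d walls, %.2f m x %.2f m\n",
              nrow(x$rooms), nrow(x$walls),
              b["xmax"] - b["xmin"], b["ymax"] - b["ymin"]))
  print(x$rooms, row.names = FALSE)
  invisible(x)
}

#' Room label at a point
#'
#' @param plan a [floorplan()].
#' @param x,y coordinates in metres (vectorised).
#' @return Character vector of room labels; `NA` for points outside all rooms.
#' @export
room_at <- function(plan, x, y) {
  stopifnot(inherits(plan, "floorplan"))
  r <- plan$rooms
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(r))) {
    inside <- x >= r$xmin[i] & x < r$xmax[i] & y >= r$ymin[i] & y < r$ymax[i]
    out[inside] <- r$room[i]
  }
  out
}

#' The default five-room evaluation floorplan
#'
#' An 8.6 m x 9.35 m single-floor house (80.41 m^2) with five rooms: kitchen,
#' living room, bedroom, bathroom and hall. The kitchen/living-room boundary
#' deliberately carries no wall segment (an open-plan archway), so the
#' propagation model attenuates across every internal boundary except that one.
#'
#' @return A [floorplan()].
#' @export
default_floorplan <- function() {
  rooms <- data.frame(
    room = c("kitchen", "living_room", "bedroom", "bathroom", "hall"),
    xmin = c(0.0, 0.0, 4.3, 4.3, 4.3),
    xmax = c(4.3, 4.3, 8.6, 8.6, 8.6),
    ymin = c(5.0, 0.0, 4.7, 2.6, 0.0),
    ymax = c(9.35, 5.0, 9.35, 4.7, 2.6),
    stringsAsFactors = FALSE
  )
  walls <- data.frame(
    # vertical spine between the west (kitchen/living) and east rooms
    x0 = c(4.3, 4.3, 4.3),
    y0 = c(0.0, 2.6, 4.7),
    x1 = c(4.3, 4.3, 4.3),
    y1 = c(2.6, 4.7, 9.35),
    stringsAsFactors = FALSE
  )
  walls <- rbind(walls, data.frame(
    # east-side internal walls: hall/bathroom and bathroom/bedroom
    x0 = c(4.3, 4.3), y0 = c(2.6, 4.7), x1 = c(8.6, 8.6), y1 = c(2.6, 4.7)
  ))
  # note: no wall on the kitchen/living_room boundary (y = 5.0, open plan)
  floorplan(rooms, walls)
}

# counts how many wall segments the sight line (x0,y0)-(x1,y1) crosses
walls_crossed <- function(plan, x0, y0, x1, y1) {
  w <- plan$walls
  if (nrow(w) == 0L) return(0L)
  n <- 0L
  for (i in seq_len(nrow(w))) {
    if (segments_intersect(x0, y0, x1, y1, w$x0[i], w$y0[i], w$x1[i], w$y1[i]))
      n <- n + 1L
  }
  n
}

# proper segment intersection via orientation tests; shared endpoints count
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  orient <- function(px, py, qx, qy, rx, ry)
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(px, py, qx, qy, rx, ry)
    orient(px, py, qx, qy, rx, ry) == 0 &&
      min(px, qx) <= rx && rx <= max(px, qx) &&
      min(py, qy) <= ry && ry <= max(py, qy)
  on_seg(ax, ay, bx, by, cx, cy) || on_seg(ax, ay, bx, by, dx, dy) ||
    on_seg(cx, cy, dx, dy, ax, ay) || on_seg(cx, cy, dx, dy, bx, by)
}

#' Place one beacon per room
#'
#' Beacons are placed at room centroids. Placements closer than the minimum
#' spacing are rejected with an error: spacing is what makes per-room
#' fingerprints discriminable, so the helper enforces it rather than warn.
#'
#' @param plan a [floorplan()].
#' @param p0 reference received power at 1 m, dBm (recycled over beacons).
#' @param min_spacing minimum pairwise beacon distance in metres (default 2).
#' @param positions optional data.frame `beacon,x,y` overriding the one-per-room
#'   default, e.g. to place two beacons in the largest rooms.
#' @return data.frame with columns `beacon`, `x`, `y`, `p0`.
#' @export
place_beacons <- function(plan, p0 = -55, min_spacing = 2, positions = NULL) {
  stopifnot(inherits(plan, "floorplan"))
  if (is.null(positions)) {
    r <- plan$rooms
    positions <- data.frame(
      beacon = paste0("b_", r$room),
      x = (r$xmin + r$xmax) / 2,
      y = (r$ymin + r$ymax) / 2,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("beacon", "x", "y") %in% names(positions)))
  positions$beacon <- as.character(positions$beacon)
  if (anyDuplicated(positions$beacon)) stop("beacon ids must be unique")
  n <- nrow(positions)
  if (n > 1) {
    d <- as.matrix(stats::dist(positions[, c("x", "y")]))
    diag(d) <- Inf
    if (min(d) < min_spacing)
      stop(sprintf("beacon spacing %.2f m below the %.1f m minimum",
                   min(d), min_spacing))
  }
  positions$p0 <- rep_len(p0, n)
  positions
}
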