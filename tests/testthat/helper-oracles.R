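# Independent oracles and small fixture builders. The perimeter oracle
# re-implements Moore-neighbor contour tracing from the definition (named
# compass directions, coordinate pairs, Jacob-style termination) without
# sharing any code with the package internals, so the circularity
# equivalence check compares two independent codings of the same estimator.

oracle_perimeter <- function(rows, cols) {
  if (length(rows) == 1L) return(0)
  pts <- paste(rows, cols)
  has <- function(r, c) paste(r, c) %in% pts
  compass <- list(N = c(-1L, 0L), NE = c(-1L, 1L), E = c(0L, 1L),
                  SE = c(1L, 1L), S = c(1L, 0L), SW = c(1L, -1L),
                  W = c(0L, -1L), NW = c(-1L, -1L))
  dir_names <- names(compass)
  dir_of <- function(v) dir_names[vapply(compass, function(d)
    all(d == v), logical(1))]
  sr <- min(rows); sc <- min(cols[rows == sr])
  cur <- c(sr, sc)
  back <- c(sr, sc - 1L)
  state0 <- c(cur, back)
  total <- 0
  for (step in seq_len(8L * length(rows) + 8L)) {
    start_dir <- dir_of(back - cur)
    ord <- c(match(start_dir, dir_names):8L,
             seq_len(match(start_dir, dir_names) - 1L))
    ord <- ord[-1L]                       # skip the backtrack cell itself
    prev_cell <- back
    nxt <- NULL
    for (j in c(ord, match(start_dir, dir_names))) {
      cell <- cur + compass[[j]]
      if (has(cell[1], cell[2])) { nxt <- cell; break }
      prev_cell <- cell
    }
    if (is.null(nxt)) return(0)
    total <- total + sqrt(sum((nxt - cur)^2))
    back <- prev_cell
    cur <- nxt
    if (all(c(cur, back) == state0)) return(total)
  }
  total
}

oracle_circularity <- function(pixels, h) {
  rows <- ((pixels - 1L) %% h) + 1L
  cols <- ((pixels - 1L) %/% h) + 1L
  a <- length(pixels)
  p <- oracle_perimeter(rows, cols)
  if (p == 0) return(1)
  min(1, 4 * pi * a / p^2)
}

# uniform calibrated image fixture
uniform_image <- function(h, w, rgb, state = "calibrated") {
  px <- array(rep(rgb, each = h * w), dim = c(h, w, 3))
  skin_image(px, bit_depth_origin = 16L, color_state = state)
}

# logical mask from a pixel predicate on (row, col)
mask_from <- function(h, w, pred) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  matrix(pred(g$r, g$c), h, w)
}

# minimal valid metric-record row builder
make_records <- function(subject, days, timepoints = c("morning_wake",
                         "morning_wash", "evening_wash"),
                         metric = "pore_area", value) {
  g <- expand.grid(subject_id = subject, study_day = days,
                   timepoint = timepoints, stringsAsFactors = FALSE)
  data.frame(subject_id = g$subject_id, study_day = g$study_day,
             week_index = week_from_day(g$study_day),
             timepoint = g$timepoint, face_side = NA_character_,
             metric = metric,
             value_au = if (is.function(value)) value(g) else value)
}
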