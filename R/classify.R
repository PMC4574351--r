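#' Configuration of the phase classifier
#'
#' Thresholds of the event-classification procedure.  An assembly or
#' disassembly event is a continuous phase producing a net length change of
#' at least `min_net_change` whose length-vs-time profile is strongly linear
#' (absolute correlation coefficient of at least `min_fit_quality`).  A pause
#' lasts at least `min_pause_points` samples without significant length
#' change (total excursion at most `pause_flatness`).
#'
#' @param min_net_change minimum |net length change| of an assembly or
#'   disassembly phase, um
#' @param min_fit_quality minimum |linear correlation| of length vs time over
#'   the phase, in (0, 1]
#' @param min_pause_points minimum number of samples in a pause
#' @param pause_flatness maximum total excursion (max - min) of a pause, um;
#'   also the largest single-sample reversal absorbed into a monotone run
#' @param max_gap_points longest undetermined gap (samples strictly between
#'   two classified phases) across which a transition is still recorded
#' @return object of class `classifier_config`
#' @export
classifier_config <- function(min_net_change = 0.5, min_fit_quality = 0.85,
                              min_pause_points = 4, pause_flatness = 0.25,
                              max_gap_points = 2) {
  if (!(min_net_change > 0)) stop("min_net_change must be > 0")
  if (!(min_fit_quality > 0 && min_fit_quality <= 1)) {
    stop("min_fit_quality must be in (0, 1]")
  }
  if (min_pause_points < 2) stop("min_pause_points must be >= 2")
  if (!(pause_flatness < min_net_change)) {
    stop("pause_flatness must be smaller than min_net_change")
  }
  structure(list(min_net_change = min_net_change,
                 min_fit_quality = min_fit_quality,
                 min_pause_points = min_pause_points,
                 pause_flatness = pause_flatness,
                 max_gap_points = max_gap_points),
            class = "classifier_config")
}

# |Pearson correlation| of length against time over sample range a..b;
# a two-point segment is perfectly linear by convention
abs_cor <- function(t, l, a, b) {
  if (b - a + 1 < 3) return(1)
  lt <- l[a:b]
  if (stats::sd(lt) == 0) return(0)
  abs(stats::cor(t[a:b], lt))
}

ols_slope <- function(t, l, a, b) {
  tt <- t[a:b]; ll <- l[a:b]
  sum((tt - mean(tt)) * (ll - mean(ll))) / sum((tt - mean(tt))^2)
}

#' Segment a length trace into assembly, disassembly and pause phases
#'
#' Implements the event-classification procedure for astral microtubule
#' length traces:
#' 1. Candidate monotone runs are formed by merging consecutive inter-sample
#'    displacements of the same sign, absorbing single-sample reversals of
#'    magnitude below `pause_flatness`.
#' 2. A run becomes an assembly (or disassembly) phase when its |net length
#'    change| is at least `min_net_change` and the |linear correlation| of
#'    length against time over the run is at least `min_fit_quality`.
#' 3. Maximal remaining stretches of at least `min_pause_points` samples
#'    whose total excursion (max - min) is at most `pause_flatness` become
#'    pauses.
#' 4. Everything else is undetermined.
#' 5. Catastrophes (assembly or pause, then disassembly) and rescues
#'    (disassembly or pause, then assembly) are recorded between consecutive
#'    classified phases; undetermined gaps of up to `max_gap_points` samples
#'    are looked through, longer gaps sever adjacency.
#'
#' Phases are contiguous blocks of inter-sample intervals; consecutive
#' phases share their boundary sample, so phase durations tile the trace
#' duration exactly.
#'
#' @param trace a `length_trace` or data.frame with columns `time_s` and
#'   `length_um` (uniformly sampled)
#' @param config a [classifier_config()]
#' @return object of class `phase_segmentation`: list with elements
#'   `phases` (data.frame: kind, start, end (1-based sample indices),
#'   t_start_s, t_end_s, duration_s, rate_um_min, net_um), `transitions`
#'   (data.frame: kind, index, time_s), `trace_ref`, `dt`, `n`
#' @examples
#' t <- seq(0, 96, by = 4)
#' l <- c(seq(0.2, 1.6, length.out = 13), seq(1.6, 0.3, length.out = 13)[-1])
#' seg <- classify_trace(data.frame(time_s = t, length_um = l))
#' seg$phases
#' @export
classify_trace <- function(trace, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  t <- trace$time_s; l <- trace$length_um
  n <- length(t)
  if (n < config$min_pause_points) {
    stop("trace shorter than min_pause_points samples")
  }
  dts <- diff(t)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-7)) {
    stop("non-uniform sampling: classify_trace requires a constant sampling interval")
  }

  d <- diff(l)
  sgn <- sign(d)
  n_int <- n - 1L

  # --- step 1: monotone runs over displacement intervals -------------------
  runs <- list()
  i <- 1L
  while (i <= n_int) {
    s <- sgn[i]
    if (s == 0) { i <- i + 1L; next }  # exactly flat: left for pause search
    j <- i
    repeat {
      if (j + 1L <= n_int && sgn[j + 1L] == s) { j <- j + 1L; next }
      if (j + 2L <= n_int && sgn[j + 1L] != s &&
          abs(d[j + 1L]) < config$pause_flatness && sgn[j + 2L] == s) {
        j <- j + 2L; next
      }
      break
    }
    runs[[length(runs) + 1L]] <- c(i, j)   # intervals i..j => samples i..j+1
    i <- j + 1L
  }

  # --- step 2: promote runs to assembly / disassembly ----------------------
  assigned <- rep(NA_character_, n_int)    # phase kind owning each interval
  phase_id <- rep(NA_integer_, n_int)
  phases <- list()
  add_phase <- function(kind, a, b) {      # samples a..b, intervals a..b-1
    phases[[length(phases) + 1L]] <<- list(kind = kind, start = a, end = b)
    assigned[a:(b - 1L)] <<- kind
    phase_id[a:(b - 1L)] <<- length(phases)
  }
  for (r in runs) {
    a <- r[1]; b <- r[2] + 1L
    net <- l[b] - l[a]
    if (abs(net) >= config$min_net_change &&
        abs_cor(t, l, a, b) >= config$min_fit_quality) {
      add_phase(if (net > 0) "assembly" else "disassembly", a, b)
    }
  }

  # --- step 3: pauses in the remaining stretches ---------------------------
  free <- is.na(assigned)
  u <- 1L
  while (u <= n) {
    # a pause window starting at sample u needs intervals u.. free
    if (u <= n_int && free[u]) {
      v <- u
      lo <- l[u]; hi <- l[u]
      while (v + 1L <= n && (v <= n_int && free[v])) {
        nlo <- min(lo, l[v + 1L]); nhi <- max(hi, l[v + 1L])
        if (nhi - nlo > config$pause_flatness) break
        lo <- nlo; hi <- nhi
        v <- v + 1L
      }
      if (v - u + 1L >= config$min_pause_points) {
        add_phase("pause", u, v)
        u <- v
      } else {
        u <- u + 1L
      }
    } else {
      u <- u + 1L
    }
  }

  # --- step 4: undetermined leftovers --------------------------------------
  free <- is.na(assigned)
  if (any(free)) {
    rl <- rle(free)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in seq_along(rl$values)) {
      if (rl$values[k]) add_phase("undetermined", starts[k], ends[k] + 1L)
    }
  }

  # order phases and build the table
  ord <- order(vapply(phases, function(p) p$start, numeric(1)))
  phases <- phases[ord]
  ptab <- do.call(rbind, lapply(phases, function(p) {
    dur <- (p$end - p$start) * dt
    rate <- switch(p$kind,
                   assembly = ,
                   disassembly = ols_slope(t, l, p$start, p$end) * 60,
                   pause = 0,
                   NA_real_)
    data.frame(kind = p$kind, start = p$start, end = p$end,
               t_start_s = t[p$start], t_end_s = t[p$end],
               duration_s = dur, rate_um_min = rate,
               net_um = l[p$end] - l[p$start],
               stringsAsFactors = FALSE)
  }))

  # --- step 5: transitions --------------------------------------------------
  cls <- ptab[ptab$kind != "undetermined", , drop = FALSE]
  transitions <- data.frame(kind = character(0), index = integer(0),
                            time_s = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cls) >= 2) {
    for (k in seq_len(nrow(cls) - 1L)) {
      a <- cls[k, ]; b <- cls[k + 1L, ]
      gap <- max(0L, b$start - a$end - 1L)     # samples strictly between
      if (gap > config$max_gap_points) next
      kind <- NULL
      if (b$kind == "disassembly" && a$kind %in% c("assembly", "pause")) {
        kind <- "catastrophe"
      } else if (b$kind == "assembly" && a$kind %in% c("disassembly", "pause")) {
        kind <- "rescue"
      }
      if (!is.null(kind)) {
        transitions <- rbind(transitions,
                             data.frame(kind = kind, index = b$start,
                                        time_s = t[b$start],
                                        stringsAsFactors = FALSE))
      }
    }
  }

  structure(list(trace_ref = list(cell_id = trace$cell_id[1] %||% NA,
                                  mt_id = trace$mt_id[1] %||% NA),
                 phases = ptab, transitions = transitions,
                 dt = dt, n = n, total_duration_s = t[n] - t[1]),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("Phase segmentation of %s/%s: %d samples, %d phases, %d transitions\n",
              x$trace_ref$cell_id, x$trace_ref$mt_id, x$n, nrow(x$phases),
              nrow(x$transitions)))
  print(table(x$phases$kind))
  invisible(x)
}

#' Tabulate the phases of a segmentation
#'
#' One row per phase, in trace order, in the exchange format used by the
#' pipeline reports (`cell_id  mt_id  kind  t_start_s  t_end_s  duration_s
#' rate_um_min  net_um`).
#'
#' @param seg a [classify_trace()] result
#' @return data.frame, one row per phase
#' @export
phase_table <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  data.frame(cell_id = seg$trace_ref$cell_id, mt_id = seg$trace_ref$mt_id,
             kind = seg$phases$kind,
             t_start_s = seg$phases$t_start_s, t_end_s = seg$phases$t_end_s,
             duration_s = seg$phases$duration_s,
             rate_um_min = seg$phases$rate_um_min,
             net_um = seg$phases$net_um,
             stringsAsFactors = FALSE)
}

#' Tabulate catastrophe and rescue transitions
#'
#' @param seg a [classify_trace()] result
#' @return data.frame `cell_id mt_id kind time_s`, one row per transition
#' @export
transition_table <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  if (nrow(seg$transitions) == 0) {
    return(data.frame(cell_id = character(0), mt_id = character(0),
                      kind = character(0), time_s = numeric(0)))
  }
  data.frame(cell_id = seg$trace_ref$cell_id, mt_id = seg$trace_ref$mt_id,
             kind = seg$transitions$kind, time_s = seg$transitions$time_s,
             stringsAsFactors = FALSE)
}
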