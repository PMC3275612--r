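# Shared fixtures and independent oracles. Heavy simulated objects are
# memoized so several test files can reuse one draw.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_model <- function() memo("model", phase_model())

pop50k <- function() memo("pop50k", sample_population(default_model(), 50000, seed = 42))

fig2_mixture <- function() make_dna_mixture(0.60, 0.30, 0.10, g1_mean = 100,
                                            cv = 0.03, n_s_components = 6)

fig2_sample <- function() memo("fig2", sample_histogram(fig2_mixture(), 50000, seed = 1))

panel50k <- function(cyclin = "cyclin_a2") {
  memo(paste0("panel_", cyclin), {
    extract_panel(pop50k(), default_model(), cyclin,
                  channels = c("dna", "cyclin_a2", "cyclin_b1", "phh3"))
  })
}

# --- independent polygon geometry oracle (Sutherland-Hodgman clipping) ---
# Used to verify, by a route independent of the package's overlap
# detection, that orthogonal region bands have zero pairwise overlap area
# and zero gap. Subject polygon clipped against a convex clip polygon.
clip_polygon <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  # ensure counter-clockwise clip orientation
  if (sum((clip[c(2:n, 1), 1] - clip[, 1]) * (clip[c(2:n, 1), 2] + clip[, 2])) > 0) {
    clip <- clip[n:1, , drop = FALSE]
  }
  for (i in seq_len(n)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    isect <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2]); d2 <- c(b[1] - a[1], b[2] - a[2])
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) /
        (d1[1] * d2[2] - d1[2] * d2[1])
      p + t * d1
    }
    res <- NULL
    m <- nrow(out)
    for (j in seq_len(m)) {
      p <- out[j, ]; q <- out[if (j == m) 1 else j + 1, ]
      if (inside(q)) {
        if (!inside(p)) res <- rbind(res, isect(p, q))
        res <- rbind(res, q)
      } else if (inside(p)) {
        res <- rbind(res, isect(p, q))
      }
    }
    out <- if (is.null(res)) matrix(numeric(0), 0, 2) else res
  }
  out
}

shoelace <- function(v) {
  if (is.null(v) || nrow(v) < 3) return(0)
  n <- nrow(v); j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2)
}

clip_area <- function(a, b) shoelace(clip_polygon(a, b))
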