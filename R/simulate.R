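# Synthetic chip time-lapse generator.
#
# Renders a field of view of microfluidic embryo incubators (dark wall
# ridges around a fluid-filled trap, gate opening at the top) holding
# textured elliptical embryos that traverse pre-bean -> bean -> twitching ->
# hatching. Rendering is analytic and fully seeded, and every call returns
# the planted ground truth, so downstream detection, classification,
# mobility and fluorescence code can be validated without microscope data.

# rendering palette (16-bit-normalized intensity units)
.BF_BG       <- 0.55   # chip background, brightfield
.BF_WALL     <- 0.15   # trap wall ridges (dark)
.BF_FLUID    <- 0.60   # trap interior fluid
.BF_EMBRYO   <- 0.35   # embryo body base intensity
.BF_TEXAMP   <- 0.07   # embryo texture amplitude
.BF_CRESCENT <- 0.28   # added intensity of the bean-stage crescent
.GFP_BG      <- 0.18   # chip autofluorescence outside the trap
.EMBRYO_RY   <- 25     # embryo semi-axis along y (50 px long)
.EMBRYO_RX   <- 15     # embryo semi-axis along x (30 px wide)

#' Per-embryo simulation specification
#'
#' Declares the planted state of one incubator and, where applicable, its
#' ground-truth transition frames (0-based). `Normal` embryos carry all
#' three transitions with `bean < twitch < hatch`; `LateHatching` embryos
#' twitch but never hatch within the sequence; `Unclear` embryos are already
#' in the bean stage at frame 0 (no observable pre-bean to bean transition)
#' but twitch and hatch; `Dead` embryos are static; `Empty` incubators hold
#' no embryo.
#'
#' @param state One of `"Normal"`, `"Dead"`, `"Unclear"`, `"LateHatching"`,
#'   `"Empty"`.
#' @param bean_frame,twitch_frame,hatch_frame 0-based transition frames
#'   (`NA` where the state forbids them).
#' @param fluo_ratio Planted embryo-to-background intensity ratio in the
#'   fluorescence channel (>= 1).
#' @param jitter_amplitude Twitching displacement amplitude, px per frame.
#' @return An object of class `sim_embryo_spec`.
#' @export
sim_embryo_spec <- function(state,
                            bean_frame = NA_integer_,
                            twitch_frame = NA_integer_,
                            hatch_frame = NA_integer_,
                            fluo_ratio = 1,
                            jitter_amplitude = 3) {
  state <- match.arg(state, c("Normal", "Dead", "Unclear", "LateHatching", "Empty"))
  b <- bean_frame; tw <- twitch_frame; h <- hatch_frame
  ok <- switch(state,
    Normal       = !is.na(b) && !is.na(tw) && !is.na(h) && b < tw && tw < h,
    LateHatching = !is.na(tw) && is.na(h),
    Unclear      = is.na(b) && !is.na(tw),
    Dead         = is.na(b) && is.na(tw) && is.na(h),
    Empty        = is.na(b) && is.na(tw) && is.na(h))
  if (!ok)
    stop("transition frames inconsistent with state '", state, "'", call. = FALSE)
  if (fluo_ratio < 1) stop("fluo_ratio must be >= 1", call. = FALSE)
  structure(list(state = state,
                 bean_frame = as.integer(b), twitch_frame = as.integer(tw),
                 hatch_frame = as.integer(h), fluo_ratio = fluo_ratio,
                 jitter_amplitude = jitter_amplitude),
            class = "sim_embryo_spec")
}

#' Synthetic chip configuration
#'
#' Geometry, imaging cadence and noise level of the simulated field of view.
#' Defaults emulate the study conditions: six incubators per field, one
#' frame every 5 min for 12 h (144 frames), 0.35 um/px so a 70 um patch is
#' 200 px, and mild Gaussian sensor noise.
#'
#' @param n_incubators Incubators per field of view.
#' @param incubator_pitch Centre-to-centre spacing, px.
#' @param trap_width,trap_height Outer trap dimensions, px.
#' @param wall_thickness Trap wall thickness, px.
#' @param gate_gap Width of the gate opening in the top wall, px.
#' @param noise_sigma SD of additive Gaussian sensor noise
#'   (16-bit-normalized units).
#' @param frame_count Number of frames.
#' @param frame_interval Minutes per frame.
#' @param pixel_size Micrometres per pixel.
#' @param frame_height Field-of-view height, px.
#' @param margin Horizontal margin flanking the incubator row, px.
#' @param channels `"brightfield"` or `c("brightfield", "gfp")`.
#' @param seed Integer RNG seed; output is bit-identical for a fixed seed.
#' @return An object of class `sim_chip_config`.
#' @export
sim_chip_config <- function(n_incubators = 6L,
                            incubator_pitch = 220L,
                            trap_width = 48L,
                            trap_height = 68L,
                            wall_thickness = 6L,
                            gate_gap = 10L,
                            noise_sigma = 0.01,
                            frame_count = 144L,
                            frame_interval = 5,
                            pixel_size = 0.35,
                            frame_height = 300L,
                            margin = 120L,
                            channels = "brightfield",
                            seed = 1L) {
  stopifnot(n_incubators >= 1, noise_sigma >= 0, frame_count >= 1,
            frame_interval > 0, all(channels %in% c("brightfield", "gfp")))
  structure(list(n_incubators = as.integer(n_incubators),
                 incubator_pitch = as.integer(incubator_pitch),
                 trap_width = as.integer(trap_width),
                 trap_height = as.integer(trap_height),
                 wall_thickness = as.integer(wall_thickness),
                 gate_gap = as.integer(gate_gap),
                 noise_sigma = noise_sigma,
                 frame_count = as.integer(frame_count),
                 frame_interval = frame_interval,
                 pixel_size = pixel_size,
                 frame_height = as.integer(frame_height),
                 margin = as.integer(margin),
                 channels = channels,
                 seed = as.integer(seed)),
            class = "sim_chip_config")
}

# run `expr` under a private, seeded RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# quantize to the 16-bit camera grid after clipping to [0, 1]
.quantize16 <- function(x) {
  round(pmin(pmax(x, 0), 1) * 65535) / 65535
}

# seeded per-embryo appearance parameters (texture + twitch offsets);
# twitching is modeled as frame-to-frame jerks of alternating direction
# whose magnitude stays within [0.75, 1] x jitter_amplitude, so the onset
# of twitching produces a sustained step in the mobility function rather
# than a ramp
.draw_embryo_params <- function(spec, frame_count) {
  alt <- rep(c(1, -1), length.out = frame_count)
  sx <- sample(c(-1, 1), 1)
  sy <- sample(c(-1, 1), 1)
  list(freq = runif(3, 0.5, 1.2),
       phase = runif(3, 0, 2 * pi),
       dx = sx * alt * spec$jitter_amplitude * runif(frame_count, 0.75, 1),
       dy = sy * alt * spec$jitter_amplitude * runif(frame_count, 0.75, 1),
       flick = runif(frame_count, 0, 2 * pi))
}

# smooth granular texture as a function of embryo-local coordinates
.embryo_texture <- function(u, v, pars, flick = 0) {
  .BF_TEXAMP * (sin(u * pars$freq[1] + pars$phase[1] + flick) +
                sin(v * pars$freq[2] + pars$phase[2]) +
                sin((u + v) * pars$freq[3] + pars$phase[3])) / 3
}

# draw the static trap (walls + fluid interior + gate) onto a canvas;
# (cy, cx) are 1-based centre coordinates
.render_trap <- function(canvas, cy, cx, config, channel = "brightfield") {
  ohx <- config$trap_width %/% 2L
  ohy <- config$trap_height %/% 2L
  ihx <- ohx - config$wall_thickness
  ihy <- ohy - config$wall_thickness
  or <- (cy - ohy):(cy + ohy); oc <- (cx - ohx):(cx + ohx)
  ir <- (cy - ihy):(cy + ihy); ic <- (cx - ihx):(cx + ihx)
  g <- config$gate_gap %/% 2L
  if (channel == "brightfield") {
    canvas[or, oc] <- .BF_WALL
    canvas[ir, ic] <- .BF_FLUID
    canvas[(cy - ohy):(cy - ihy - 1L), (cx - g):(cx + g)] <- .BF_FLUID
  } else {
    canvas[or, oc] <- 0    # trap walls and fluid are non-fluorescent
  }
  canvas
}

# paint one embryo onto a canvas; renders only pixels inside the trap
# interior so jitter never spills onto the walls
.render_embryo <- function(canvas, cy, cx, config, stage, pars, t,
                           jitter = FALSE, channel = "brightfield",
                           fluo_ratio = 1) {
  ihx <- config$trap_width %/% 2L - config$wall_thickness
  ihy <- config$trap_height %/% 2L - config$wall_thickness
  dy <- if (jitter) pars$dy[t] else 0
  dx <- if (jitter) pars$dx[t] else 0
  flick <- if (jitter) pars$flick[t] else 0
  rows <- (cy - ihy):(cy + ihy)
  cols <- (cx - ihx):(cx + ihx)
  u <- outer(rows - cy - dy, rep(1, length(cols)))
  v <- outer(rep(1, length(rows)), cols - cx - dx)
  inside <- (u / .EMBRYO_RY)^2 + (v / .EMBRYO_RX)^2 <= 1
  if (channel == "brightfield") {
    val <- .BF_EMBRYO + .embryo_texture(u, v, pars, flick)
    if (stage == "bean") {
      # crescent: outer ellipse minus an inner ellipse shifted sideways
      inner <- (u / (.EMBRYO_RY - 7))^2 + ((v - 5) / (.EMBRYO_RX - 7))^2 <= 1
      val[inside & !inner] <- val[inside & !inner] + .BF_CRESCENT
    }
  } else {
    val <- matrix(fluo_ratio * .GFP_BG, length(rows), length(cols))
  }
  sub <- canvas[rows, cols]
  sub[inside] <- val[inside]
  canvas[rows, cols] <- sub
  canvas
}

# developmental stage of an embryo spec at 0-based frame t0:
# "absent", "prebean", "bean" (+ attribute jitter = twitching)
.embryo_stage_at <- function(spec, t0) {
  st <- spec$state
  if (st == "Empty") return(list(stage = "absent", jitter = FALSE))
  if (st == "Dead")  return(list(stage = "prebean", jitter = FALSE))
  if (st == "Unclear") {
    if (!is.na(spec$hatch_frame) && t0 >= spec$hatch_frame)
      return(list(stage = "absent", jitter = FALSE))
    return(list(stage = "bean", jitter = t0 >= spec$twitch_frame))
  }
  # Normal / LateHatching
  if (!is.na(spec$hatch_frame) && t0 >= spec$hatch_frame)
    return(list(stage = "absent", jitter = FALSE))
  if (t0 < spec$bean_frame) return(list(stage = "prebean", jitter = FALSE))
  list(stage = "bean", jitter = t0 >= spec$twitch_frame)
}

#' Simulate a chip field of view
#'
#' Renders a seeded synthetic time-lapse of `n_incubators` embryo
#' incubators, one embryo spec per incubator, and returns the sequence
#' together with the full planted ground truth. Static embryos (and all
#' frames at `noise_sigma = 0`) are bit-identical across frames before
#' noise; a hatched incubator is rendered empty from the hatch frame on;
#' twitching is seeded per-frame displacement of amplitude
#' `jitter_amplitude`. The optional GFP channel renders embryo pixels at
#' `fluo_ratio` times the chip autofluorescence level with a dark
#' (non-fluorescent) trap.
#'
#' @param config A [sim_chip_config()].
#' @param embryos List of [sim_embryo_spec()], one per incubator.
#' @return A list with elements `sequence` (a [time_lapse_sequence()]),
#'   `truth` (tibble: incubator index, state, transition frames, fluo_ratio,
#'   true centroid x/y in 0-based pixels) and `locations` (tibble: index,
#'   x, y).
#' @export
simulate_chip <- function(config, embryos) {
  stopifnot(inherits(config, "sim_chip_config"))
  if (length(embryos) != config$n_incubators)
    stop("need exactly one embryo spec per incubator (",
         config$n_incubators, ")", call. = FALSE)
  for (e in embryos) {
    stopifnot(inherits(e, "sim_embryo_spec"))
    fr <- c(e$bean_frame, e$twitch_frame, e$hatch_frame)
    if (any(fr >= config$frame_count, na.rm = TRUE))
      stop("transition frames must lie before frame_count", call. = FALSE)
  }
  H <- config$frame_height
  W <- 2L * config$margin + (config$n_incubators - 1L) * config$incubator_pitch
  Tn <- config$frame_count
  cy0 <- H %/% 2L                                  # 0-based centre row
  cx0 <- config$margin + (seq_len(config$n_incubators) - 1L) * config$incubator_pitch

  .with_seed(config$seed, {
    pars <- lapply(embryos, .draw_embryo_params, frame_count = Tn)

    out <- list()
    for (ch in config$channels) {
      template <- matrix(if (ch == "brightfield") .BF_BG else .GFP_BG, H, W)
      for (i in seq_len(config$n_incubators))
        template <- .render_trap(template, cy0 + 1L, cx0[i] + 1L, config, ch)
      arr <- array(0, dim = c(H, W, Tn))
      for (t in seq_len(Tn)) {
        fr <- template
        for (i in seq_len(config$n_incubators)) {
          st <- .embryo_stage_at(embryos[[i]], t - 1L)
          if (st$stage != "absent")
            fr <- .render_embryo(fr, cy0 + 1L, cx0[i] + 1L, config, st$stage,
                                 pars[[i]], t, jitter = st$jitter, channel = ch,
                                 fluo_ratio = embryos[[i]]$fluo_ratio)
        }
        if (config$noise_sigma > 0)
          fr <- fr + rnorm(length(fr), 0, config$noise_sigma)
        arr[, , t] <- .quantize16(fr)
      }
      out[[ch]] <- arr
    }
    seq <- time_lapse_sequence(out, config$frame_interval, config$pixel_size)
    truth <- tibble::tibble(
      incubator = seq_along(embryos) - 1L,
      state = vapply(embryos, function(e) e$state, ""),
      bean_frame = vapply(embryos, function(e) e$bean_frame, integer(1)),
      twitch_frame = vapply(embryos, function(e) e$twitch_frame, integer(1)),
      hatch_frame = vapply(embryos, function(e) e$hatch_frame, integer(1)),
      fluo_ratio = vapply(embryos, function(e) e$fluo_ratio, numeric(1)),
      x = cx0, y = rep(cy0, length(embryos)))
    list(sequence = seq,
         truth = truth,
         locations = tibble::tibble(index = truth$incubator,
                                    x = truth$x, y = truth$y))
  })
}

#' Ground-truth trap interior mask for one incubator patch
#'
#' The exact interior (fluid region inside the walls, gate excluded) of a
#' trap centred in a `patch_size` square patch, as rendered by
#' [simulate_chip()]. Used to validate fluorescence masks against known
#' geometry.
#'
#' @param config A [sim_chip_config()].
#' @param patch_size Patch side, px.
#' @return A binary matrix (1 = interior).
#' @export
sim_interior_mask <- function(config, patch_size = 200L) {
  ihx <- config$trap_width %/% 2L - config$wall_thickness
  ihy <- config$trap_height %/% 2L - config$wall_thickness
  c0 <- patch_size %/% 2L + 1L
  m <- matrix(0L, patch_size, patch_size)
  m[(c0 - ihy):(c0 + ihy), (c0 - ihx):(c0 + ihx)] <- 1L
  m
}

#' Generate a labeled training set of incubator patches
#'
#' Renders `n_per_class` single-incubator patches for each of the three
#' classifier classes — empty incubator, pre-bean embryo, bean-stage
#' embryo — with randomized embryo texture and a few pixels of centring
#' jitter, at the noise level of `config`. Mirrors the three-class design
#' used for training the stage classifier (class imbalance is allowed:
#' `n_per_class` may be a vector of three counts).
#'
#' @param config A [sim_chip_config()].
#' @param n_per_class Patches per class (length 1 or 3, order Empty,
#'   PreBean, Bean).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param patch_size Patch side, px.
#' @return A tibble with columns `label` (factor Empty/PreBean/Bean) and
#'   `patch` (list of `patch_size` square matrices).
#' @export
make_training_set <- function(config, n_per_class, seed = config$seed,
                              patch_size = 200L) {
  stopifnot(all(n_per_class >= 1))
  classes <- c("Empty", "PreBean", "Bean")
  n <- if (length(n_per_class) == 1) rep(n_per_class, 3) else n_per_class
  stopifnot(length(n) == 3)
  c0 <- patch_size %/% 2L + 1L
  .with_seed(seed, {
    rows <- list()
    for (k in seq_along(classes)) {
      for (j in seq_len(n[k])) {
        patch <- matrix(.BF_BG, patch_size, patch_size)
        patch <- .render_trap(patch, c0, c0, config)
        if (classes[k] != "Empty") {
          spec <- sim_embryo_spec("Dead")
          pars <- .draw_embryo_params(spec, 1L)
          off <- round(runif(2, -4, 4))
          pars$dx[1] <- off[1]; pars$dy[1] <- off[2]
          patch <- .render_embryo(patch, c0, c0, config,
                                  stage = if (classes[k] == "Bean") "bean" else "prebean",
                                  pars = pars, t = 1L, jitter = TRUE)
        }
        if (config$noise_sigma > 0)
          patch <- patch + rnorm(length(patch), 0, config$noise_sigma)
        rows[[length(rows) + 1L]] <- list(label = classes[k],
                                          patch = .quantize16(patch))
      }
    }
    tibble::tibble(
      label = factor(vapply(rows, function(r) r$label, ""), levels = classes),
      patch = lapply(rows, function(r) r$patch))
  })
}

#' Draw a random cohort of embryo specifications
#'
#' Samples `n` per-incubator specs with a fixed state composition
#' (rounded from `mix`) and seeded random transition frames chosen so all
#' transitions fit inside `frame_count` frames: bean at frames 12-40,
#' twitching 10-30 frames later, hatching 30-70 frames after that.
#'
#' @param n Number of incubators.
#' @param frame_count Sequence length the specs must fit into (>= 144
#'   recommended for the default frame ranges).
#' @param mix Named state proportions (Normal, Dead, Unclear, LateHatching,
#'   Empty); rounded to counts summing to `n`.
#' @param seed Integer seed.
#' @return List of `n` [sim_embryo_spec()] objects in shuffled order.
#' @export
random_embryo_specs <- function(n, frame_count = 144L,
                                mix = c(Normal = 0.5, Dead = 0.125,
                                        Unclear = 0.125, LateHatching = 0.125,
                                        Empty = 0.125),
                                seed = 1L) {
  counts <- round(mix * n)
  counts[1] <- n - sum(counts[-1])
  .with_seed(seed, {
    states <- sample(rep(names(counts), counts))
    lapply(states, function(st) {
      switch(st,
        Normal = {
          b <- sample(12:40, 1); tw <- b + sample(10:30, 1)
          sim_embryo_spec("Normal", b, tw, tw + sample(30:70, 1))
        },
        Unclear = {
          tw <- sample(20:50, 1)
          sim_embryo_spec("Unclear", twitch_frame = tw,
                          hatch_frame = tw + sample(30:70, 1))
        },
        LateHatching = {
          b <- sample(12:40, 1)
          sim_embryo_spec("LateHatching", bean_frame = b,
                          twitch_frame = b + sample(10:30, 1))
        },
        sim_embryo_spec(st))
    })
  })
}
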