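## Ground-truthed synthetic recordings, cohorts, and structure fixtures.
## Generators are pure functions of (inputs, seed): the RNG state of the
## session is saved and restored around every draw.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Recording noise specification
#'
#' Additive i.i.d. Gaussian noise per channel plus an optional linear
#' bleach drift applied to the raw fluorescence before dF/F
#' normalization. Defaults emulate the visual quality of published oocyte
#' recordings: current noise 2\% of a unit peak, dF/F noise 5e-4.
#'
#' @param current_sigma current noise sd (current units).
#' @param dF_sigma fluorescence noise sd (dF/F units).
#' @param bleach_rate linear bleach, fraction of raw fluorescence per
#'   second.
#' @param seed integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(current_sigma = 0.02, dF_sigma = 5e-4,
                       bleach_rate = 0, seed = 1L) {
  if (current_sigma < 0 || dF_sigma < 0 || bleach_rate < 0)
    stop("noise parameters must be >= 0")
  structure(list(current_sigma = current_sigma, dF_sigma = dF_sigma,
                 bleach_rate = bleach_rate, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Cohort specification for multi-cell synthetic data
#'
#' Emulates the per-oocyte variability behind the kinetics correlation
#' analysis: each cell carries a lognormal multiplier (sdlog =
#' `model_jitter`) on its gate time constants, and the fluorescence
#' kinetics are planted such that the expected regression of the dF rise
#' time on the current rise time has slope `target_slope` (slope < 1:
#' the reported conformational change is faster than pore opening).
#'
#' @param n_cells number of cells (>= 3).
#' @param factor_truth ground-truth [fluorescence_factors()].
#' @param model_jitter lognormal sd of the per-cell kinetics multiplier.
#' @param target_slope planted RT_F-vs-RT_I slope.
#' @param seed master seed; per-cell streams use `seed + cell index`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells = 8, factor_truth =
                          fluorescence_factors(F_O = -1, F_OD = -1),
                        model_jitter = 0.3, target_slope = 1.0, seed = 1L) {
  if (n_cells < 3) stop("'n_cells' must be >= 3")
  if (model_jitter < 0) stop("'model_jitter' must be >= 0")
  stopifnot(inherits(factor_truth, "vcf_factors"))
  structure(list(n_cells = as.integer(n_cells), factor_truth = factor_truth,
                 model_jitter = model_jitter, target_slope = target_slope,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

new_recording <- function(time, current, dF_over_F, meta) {
  if (length(time) != length(current) || length(time) != length(dF_over_F))
    stop("recording vectors must share their length")
  if (any(diff(time) <= 0)) stop("recording time must be strictly increasing")
  if (is.null(meta$pulse_start) || is.null(meta$pulse_end) ||
      meta$pulse_start < min(time) || meta$pulse_end > max(time))
    stop("pulse window must lie within the recorded time range")
  structure(list(time = time, current = current, dF_over_F = dF_over_F,
                 meta = meta),
            class = "vcf_recording")
}

#' @export
print.vcf_recording <- function(x, ...) {
  cat(sprintf("VCF recording '%s': %d samples, %.3g s, pulse %g -> pH %.2f\n",
              if (is.null(x$meta$label)) "?" else x$meta$label,
              length(x$time), max(x$time), x$meta$pulse_start,
              x$meta$stimulation_pH))
  invisible(x)
}

scale_gate_tau <- function(gate, m) {
  gate_parameters(gate$pH50, gate$hill_n, gate$tau_alkaline * m,
                  gate$tau_acidic * m, gate$tau_pH50, gate$tau_hill_n)
}

scale_model_tau <- function(model, m) {
  channel_model(scale_gate_tau(model$activation, m),
                scale_gate_tau(model$sensitization, m),
                current_scale = model$current_scale,
                current_sign = model$current_sign)
}

#' Generate one synthetic current + fluorescence recording
#'
#' Simulates the state trajectory, renders the open-state current and the
#' factor-weighted dF signal, applies the bleach drift to the raw
#' fluorescence, adds independent Gaussian noise per channel, and
#' re-normalizes the fluorescence to dF/F over the conditioning baseline.
#' The metadata records the full ground truth; identical seeds give
#' bitwise-identical recordings.
#'
#' @param model an [channel_model()].
#' @param factors ground-truth [fluorescence_factors()].
#' @param protocol a [ph_protocol()].
#' @param noise a [noise_spec()].
#' @param label recording label stored in the metadata.
#' @param fluor_model optional second [channel_model()] driving the
#'   fluorescence kinetics (used by [generate_cohort()] to plant dF
#'   kinetics differing from the current kinetics); defaults to `model`.
#' @return A `vcf_recording`.
#' @export
generate_recording <- function(model, factors, protocol, noise = noise_spec(),
                               label = "synthetic", fluor_model = model) {
  stopifnot(inherits(noise, "noise_spec"))
  traj <- integrate_gates(model, protocol)
  traj_F <- if (identical(fluor_model, model)) traj
  else integrate_gates(fluor_model, protocol)
  I0 <- simulate_current(traj, model)
  dF0 <- synthesize_dF(traj_F, factors)
  win <- protocol_pulse_window(protocol)
  n <- length(traj$time)
  with_seed(noise$seed, {
    current <- I0 + rnorm(n, 0, noise$current_sigma)
    F0 <- 1
    raw <- F0 * (1 + dF0) * (1 - noise$bleach_rate * traj$time) +
      rnorm(n, 0, noise$dF_sigma * F0)
    dF <- normalize_fluorescence(raw, traj$time, c(0, win[1]))
    new_recording(traj$time, current, dF, meta = list(
      label = label, conditioning_pH = protocol$conditioning_pH,
      stimulation_pH = protocol$segments$pH[2],
      pulse_start = win[1], pulse_end = win[2], seed = noise$seed,
      truth = list(factors = unclass(factors),
                   noise = unclass(noise))))
  })
}

#' Generate a cohort of synthetic recordings
#'
#' Each cell draws a lognormal kinetics multiplier `m_i` applied to the
#' gate time constants of its current model, spreading the current rise
#' times across the cohort as per-oocyte variability does. The cell's
#' fluorescence kinetics are then planted so that its noise-free dF onset
#' rise time equals `target_slope` times its own noise-free current rise
#' time: with the default activation-gate factor truth the dF trace is a
#' pure exponential, whose time-constant multiplier is solved from the
#' measured current rise time. The expected regression of RT_F on RT_I
#' therefore passes through the origin with the planted slope. Per-cell
#' noise streams derive from the master seed by fixed increments.
#'
#' @param model the base [channel_model()].
#' @param spec a [cohort_spec()].
#' @param protocol a [ph_protocol()]; the default uses an instantaneous
#'   pH step so that rise times are set by the gate kinetics alone.
#' @param noise noise applied to every cell (per-cell seeds override the
#'   seed field).
#' @return list of `vcf_recording` objects, one per cell.
#' @export
generate_cohort <- function(model, spec,
                            protocol = pulse_protocol(fall_time = 0,
                                                      post_s = 2),
                            noise = noise_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- with_seed(spec$seed,
                 exp(rnorm(spec$n_cells, 0, spec$model_jitter)))
  test_pH <- protocol$segments$pH[2]
  tau_a_test <- gate_time_constant(test_pH, model$activation)
  win <- protocol_pulse_window(protocol)
  lapply(seq_len(spec$n_cells), function(i) {
    cell_model <- scale_model_tau(model, m[i])
    ## noise-free current rise time of this cell, then the fluorescence
    ## time-constant multiplier that plants RT_F = target_slope * RT_I
    traj_i <- integrate_gates(cell_model, protocol)
    RT_I0 <- rise_time(traj_i$time, simulate_current(traj_i, cell_model),
                       win)
    beta <- spec$target_slope * RT_I0 / (log(9) * tau_a_test)
    fluor_model <- scale_model_tau(model, beta)
    cell_noise <- noise_spec(noise$current_sigma, noise$dF_sigma,
                             noise$bleach_rate, seed = spec$seed + i)
    rec <- generate_recording(cell_model, spec$factor_truth, protocol,
                              cell_noise,
                              label = sprintf("cell%02d", i),
                              fluor_model = fluor_model)
    rec$meta$truth$kinetics_multiplier <- m[i]
    rec$meta$truth$target_slope <- spec$target_slope
    rec$meta$truth$RT_I_noise_free <- RT_I0
    rec
  })
}

#' Rise-time pairs of a cohort
#'
#' Convenience wrapper: runs [analyze_recording()] on every recording and
#' collects the (RT_I, RT_F) pairs entering
#' [correlation_classification()].
#'
#' @param recordings list of recordings.
#' @param ... passed to [analyze_recording()].
#' @return data frame with columns `RT_I` and `RT_F`.
#' @export
cohort_rt_pairs <- function(recordings, ...) {
  out <- do.call(rbind, lapply(recordings, function(rec) {
    ks <- analyze_recording(rec, ...)
    data.frame(RT_I = ks$RT_I_on, RT_F = ks$RT_F_on)
  }))
  rownames(out) <- NULL
  out
}

#' Write minimal trimeric structure fixtures with planted distances
#'
#' Writes one PDB file per functional state (closed, open, desensitized)
#' containing three chains with a Cbeta atom for every requested residue,
#' positioned so that the measured Cbeta distances equal the planted
#' values. These are synthetic geometric fixtures: chains carry no
#' stereochemical realism beyond the atom naming the readers require.
#'
#' Each pair occupies its own z-plane and each subunit copy its own y-row,
#' so pairs and interfaces cannot interact; residues must therefore not be
#' shared between pairs.
#'
#' @param pairs data frame with columns `residue1`, `residue2` and logical
#'   `intersubunit`.
#' @param distances named list with elements `closed`, `open`,
#'   `desensitized`; each either a vector of one distance per pair
#'   (replicated over the three interfaces) or an `n_pairs x 3` matrix of
#'   per-interface distances (A, > 0).
#' @param dir output directory (created if missing).
#' @param seed kept for interface symmetry; the construction is
#'   deterministic.
#' @return named character vector of the three file paths.
#' @export
generate_structure_fixture <- function(pairs, distances, dir, seed = 1L) {
  pairs <- as.data.frame(pairs)
  res_all <- c(pairs$residue1, pairs$residue2)
  if (anyDuplicated(vapply(res_all, parse_residue, integer(1))))
    stop("residues must not be shared between planted pairs")
  need <- c("closed", "open", "desensitized")
  if (!all(need %in% names(distances)))
    stop("'distances' must contain closed, open and desensitized")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chains <- c("A", "B", "C")
  paths <- setNames(file.path(dir, paste0(need, ".pdb")), need)
  for (st in need) {
    d <- distances[[st]]
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(pairs), ncol = 3)
    if (any(d <= 0)) stop("unrealizable geometry: distances must be > 0")
    atom <- list(resno = integer(0), chain = character(0),
                 xyz = NULL)
    for (p in seq_len(nrow(pairs))) {
      z <- 10 * p
      r1 <- parse_residue(pairs$residue1[p])
      r2 <- parse_residue(pairs$residue2[p])
      inter <- isTRUE(as.logical(pairs$intersubunit[p]))
      for (k in 1:3) {
        y <- 1000 * (k - 1)
        ## residue 1 of chain k sits at (0, y, z); its partner copy -- in
        ## the same chain (intra) or the next chain (inter) -- at
        ## (d, y, z). Partner chain: cyclic A->B->C->A.
        pc <- if (inter) chains[c(2, 3, 1)][k] else chains[k]
        atom$resno <- c(atom$resno, r1, r2)
        atom$chain <- c(atom$chain, chains[k], pc)
        atom$xyz <- rbind(atom$xyz, c(0, y, z), c(d[p, k], y, z))
      }
    }
    ord <- order(atom$chain, atom$resno)
    n <- length(atom$resno)
    bio3d::write.pdb(file = paths[[st]],
                     xyz = as.numeric(t(atom$xyz[ord, , drop = FALSE])),
                     resno = atom$resno[ord], chain = atom$chain[ord],
                     resid = rep("ALA", n), elety = rep("CB", n),
                     eleno = seq_len(n))
  }
  paths
}

#' Write a recording to CSV with a JSON metadata sidecar
#'
#' The CSV holds, in this fixed order, the columns `time_s`, `current`,
#' `dF_over_F`; the sidecar (same path with extension `.json`) carries the
#' metadata including the ground truth, serialized at full precision.
#'
#' @param recording a `vcf_recording`.
#' @param path CSV file path (`.csv`).
#' @return invisibly, the two file paths.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "vcf_recording"))
  df <- data.frame(time_s = recording$time, current = recording$current,
                   dF_over_F = recording$dF_over_F)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
            path, row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(recording$meta, sidecar, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(csv = path, json = sidecar))
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV file path; the JSON sidecar is located next to it.
#' @return A validated `vcf_recording`.
#' @export
read_recording <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "current", "dF_over_F")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("recording file misses column(s): ", paste(miss, collapse = ", "))
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) stop("metadata sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time column in ", path)
  new_recording(df$time_s, df$current, df$dF_over_F, meta)
}
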