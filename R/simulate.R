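# Full scan simulation: render + edge blur + per-slice noise + artifacts.

# Documented per-slice seeding scheme: the noise (and blotches) of slice k of
# a scan with master seed s are drawn from a stream seeded with
# slice_seed(s, k) = (s + 100003 * k) mod (2^31 - 1), so any slice is
# reproducible in isolation.
slice_seed <- function(seed, k) (as.numeric(seed) + 100003 * k) %% 2147483647

#' Simulate one CT scan of the phantom
#'
#' Renders the noiseless phantom, blurs the structure with the model's
#' point-spread Gaussian, then adds an independent colored-noise field per
#' slice (and, if the model carries them, sparse blotch artifacts). Fully
#' deterministic given `seed`.
#'
#' @param layout a [ctiq_layout()].
#' @param model a [noise_model()].
#' @param dose dose (CTDI_vol), mGy.
#' @param thickness slice thickness, mm.
#' @param n_slices number of slices.
#' @param seed integer master seed.
#' @param scan_id identifier; default encodes algorithm and dose.
#' @return An [image_stack()].
#' @export
simulate_scan <- function(layout, model, dose, thickness = 2.5,
                          n_slices = 40, seed = 1,
                          scan_id = sprintf("%s_%gmGy_%gmm_s%d", model$label,
                                            dose, thickness, seed)) {
  stopifnot(inherits(layout, "ctiq_layout"), inherits(model, "ctiq_noise_model"))
  base <- render_phantom(layout, n_slices, thickness)
  plain <- gaussian_blur(render_slice(layout, FALSE), model$edge_blur_sigma,
                         layout$pixel_spacing)
  lesioned <- gaussian_blur(render_slice(layout, TRUE), model$edge_blur_sigma,
                            layout$pixel_spacing)
  les <- lesion_slices(layout, n_slices, thickness)
  sp <- layout$pixel_spacing
  shape <- layout$grid_size
  scale <- (dose / model$d_ref)^model$dose_exponent *
    (thickness / model$thickness_ref)^model$thickness_exponent
  vox <- base$voxels
  for (k in seq_len(n_slices)) {
    structure_k <- if (k %in% les) lesioned else plain
    noise <- synthesize_noise(shape, sp, model, dose, thickness,
                              seed = slice_seed(seed, k))
    if (!is.null(model$blotch))  # continues the slice's RNG stream
      noise <- noise + blotch_field(shape, sp, model$blotch, scale)
    vox[, , k] <- structure_k + noise
  }
  image_stack(vox, sp, thickness, dose_ctdi = dose, algorithm = model$label,
              scan_id = scan_id, seed = as.integer(seed))
}

#' Simulate a full factorial study design
#'
#' Crosses algorithms x doses x repeats at one slice thickness, deriving a
#' distinct master seed per scan from the design seed
#' (`seed + 7919 * scan_index`, mod 2^31 - 1).
#'
#' @param layout a [ctiq_layout()].
#' @param models named list of [noise_model()]s.
#' @param doses vector of doses, mGy.
#' @param repeats number of repeat scans per condition.
#' @param n_slices slices per scan.
#' @param thickness slice thickness, mm.
#' @param seed design master seed.
#' @param out_dir if non-`NULL`, each stack is written as a fixture there (see
#'   [write_fixture()]) and only the manifest is returned, keeping memory flat.
#' @return A list of stacks, or (with `out_dir`) a data frame manifest.
#' @export
simulate_design <- function(layout, models, doses, repeats = 3, n_slices = 40,
                            thickness = 2.5, seed = 1, out_dir = NULL) {
  grid <- expand.grid(rep = seq_len(repeats), dose = doses,
                      model = names(models), stringsAsFactors = FALSE)
  stacks <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- models[[grid$model[i]]]
    scan_seed <- (as.numeric(seed) + 7919 * i) %% 2147483647
    id <- sprintf("%s_%gmGy_%gmm_r%d", m$label, grid$dose[i], thickness,
                  grid$rep[i])
    st <- simulate_scan(layout, m, grid$dose[i], thickness, n_slices,
                        seed = scan_seed, scan_id = id)
    rows[[i]] <- data.frame(scan_id = id, algorithm = m$label,
                            dose = grid$dose[i], thickness = thickness,
                            rep = grid$rep[i], n_slices = n_slices,
                            seed = scan_seed, stringsAsFactors = FALSE)
    if (is.null(out_dir)) stacks[[i]] <- st else write_fixture(st, out_dir)
  }
  manifest <- do.call(rbind, rows)
  if (is.null(out_dir)) {
    names(stacks) <- manifest$scan_id
    attr(stacks, "manifest") <- manifest
    stacks
  } else manifest
}
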