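#' Membrane frames
#'
#' A membrane frame is a tibble with one particle per row and columns
#' `x`, `y`, `z` (nm, wrapped into the box), `species` (e.g. `"POPC"`,
#' `"CHOL"`, `"W"`), `role` (one of `"head"`, `"tail"`, `"water"`,
#' `"polar"`) and `molecule_id` (integer grouping particles into molecules).
#' The orthorhombic periodic box is stored in the `box` attribute as three
#' positive edge lengths in nm.
#'
#' Particles with role `"water"` or `"polar"` count as polar for defect
#' detection; every lipid molecule carries exactly one head particle and at
#' least one tail particle.
#'
#' @param particles A data frame with the columns above.
#' @param box Numeric vector of three positive box edge lengths (nm).
#'
#' @return A `membrane_frame` (tibble subclass).
#' @seealso [make_flat_membrane()], [make_pore_membrane()],
#'   [make_water_wire()]
#' @export
membrane_frame <- function(particles, box) {
  particles <- as_tibble(particles)
  required <- c("x", "y", "z", "species", "role", "molecule_id")
  missing <- setdiff(required, names(particles))
  if (length(missing) > 0) {
    abort(paste0("membrane frame is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "poremech_validation_error")
  }
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) ||
      any(box <= 0)) {
    abort("`box` must be three positive edge lengths in nm.",
          class = "poremech_validation_error")
  }
  roles_ok <- particles$role %in% c("head", "tail", "water", "polar")
  if (!all(roles_ok)) {
    abort("`role` must be one of head, tail, water, polar.",
          class = "poremech_validation_error")
  }
  particles$x <- wrap_coords(particles$x, box[1])
  particles$y <- wrap_coords(particles$y, box[2])
  particles$z <- wrap_coords(particles$z, box[3])
  out <- tibble::new_tibble(particles, box = as.numeric(box),
                            class = "membrane_frame")
  validate_membrane_frame(out)
  out
}

validate_membrane_frame <- function(frame) {
  box <- frame_box(frame)
  lip <- frame[frame$role %in% c("head", "tail"), ]
  if (nrow(lip) > 0) {
    heads <- table(lip$molecule_id[lip$role == "head"])
    tails <- unique(lip$molecule_id[lip$role == "tail"])
    mols  <- unique(lip$molecule_id)
    if (any(heads != 1) || length(heads) != length(mols) ||
        !all(mols %in% tails)) {
      abort("every lipid molecule needs exactly one head and >= 1 tail particle.",
            class = "poremech_validation_error")
    }
  }
  invisible(frame)
}

#' @rdname membrane_frame
#' @param x An object.
#' @export
is_membrane_frame <- function(x) inherits(x, "membrane_frame")

#' Box edge lengths of a membrane frame
#'
#' @param frame A [membrane_frame()].
#' @return Numeric vector of three edge lengths (nm).
#' @export
frame_box <- function(frame) {
  box <- attr(frame, "box")
  if (is.null(box)) {
    abort("not a membrane frame: missing `box` attribute.",
          class = "poremech_validation_error")
  }
  box
}

# polar particles feed defect/pore detection
is_polar_role <- function(role) role %in% c("water", "polar")

#' Count lipids per species in a frame
#'
#' Helper that tabulates lipid molecules (by their head particle) per species.
#'
#' @param frame A [membrane_frame()].
#' @return A tibble with columns `species` and `n_lipids`.
#' @export
count_lipids <- function(frame) {
  frame |>
    filter(.data$role == "head") |>
    dplyr::count(.data$species, name = "n_lipids")
}

#' @export
print.membrane_frame <- function(x, ...) {
  box <- frame_box(x)
  cat(sprintf("# membrane_frame: %d particles, box %.2f x %.2f x %.2f nm\n",
              nrow(x), box[1], box[2], box[3]))
  NextMethod()
}
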