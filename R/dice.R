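#' Dice specifications for station capacity
#'
#' Every station's per-round processing capacity is generated by a die.
#' Three kinds are supported: a standard six-sided die (`standard_d6`),
#' the "4-6 die" used to model an exploited constraint (`four_to_six`:
#' an underlying D6 whose low faces are remapped 1 to 4, 2 to 5 and 3 to 6,
#' raising the mean from 3.5 to 5 while shrinking the spread), and the sum
#' of several component dice (`sum`, e.g. two D6 for an elevated resource).
#'
#' @param kind One of `"standard_d6"`, `"four_to_six"`, `"sum"`.
#' @param components For `kind = "sum"` only: a list of two or more
#'   `dice_spec` objects whose draws are added.
#' @return An object of class `dice_spec`.
#' @seealso [roll()], [dice_mean()]
#' @examples
#' roll(dice_four_to_six(), faces = 2) # remapped to 5
#' dice_mean(dice_sum(dice_d6(), dice_d6()))
#' @export
dice_spec <- function(kind = c("standard_d6", "four_to_six", "sum"),
                      components = list()) {
  kind <- match.arg(kind)
  if (kind == "sum") {
    if (length(components) < 2L)
      stop("a 'sum' dice spec needs at least two component dice", call. = FALSE)
    if (!all(vapply(components, inherits, logical(1L), "dice_spec")))
      stop("all components must be dice_spec objects", call. = FALSE)
  } else if (length(components)) {
    stop("components are only meaningful for kind = \"sum\"", call. = FALSE)
  }
  structure(list(kind = kind, components = components), class = "dice_spec")
}

#' @rdname dice_spec
#' @export
dice_d6 <- function() dice_spec("standard_d6")

#' @rdname dice_spec
#' @export
dice_four_to_six <- function() dice_spec("four_to_six")

#' @rdname dice_spec
#' @param ... For `dice_sum()`: component `dice_spec` objects.
#' @export
dice_sum <- function(...) dice_spec("sum", components = list(...))

# number of underlying physical dice behind a spec
n_dice <- function(spec) {
  if (spec$kind == "sum") sum(vapply(spec$components, n_dice, integer(1L))) else 1L
}

#' Roll a die
#'
#' Draws capacities from a [dice_spec()]. With `faces` supplied the roll is
#' scripted: `faces` gives the underlying face (1-6) of each physical die
#' and the result is deterministic (the 4-6 die applies its remap to the
#' scripted face). Without `faces`, draws come from R's RNG, so a prior
#' `set.seed()` makes the sequence reproducible.
#'
#' @param spec A [dice_spec()].
#' @param n Number of independent draws (ignored when `faces` is given).
#' @param faces Optional integer vector of underlying die faces, one per
#'   physical die in `spec`. Faces outside 1-6 are an error.
#' @return Integer vector of capacities.
#' @examples
#' roll(dice_four_to_six(), faces = 2)          # -> 5
#' roll(dice_sum(dice_d6(), dice_d6()), faces = c(3, 4)) # -> 7
#' set.seed(1); roll(dice_d6(), n = 5)
#' @export
roll <- function(spec, n = 1L, faces = NULL) {
  stopifnot(inherits(spec, "dice_spec"))
  if (!is.null(faces)) {
    faces <- as.integer(faces)
    if (anyNA(faces) || any(faces < 1L | faces > 6L))
      stop("scripted die faces must be integers between 1 and 6", call. = FALSE)
    if (length(faces) != n_dice(spec))
      stop(sprintf("dice spec uses %d physical die/dice but %d face(s) were scripted",
                   n_dice(spec), length(faces)), call. = FALSE)
    return(face_value(spec, faces))
  }
  roll_n(spec, as.integer(n))
}

roll_n <- function(spec, n) {
  switch(spec$kind,
    standard_d6 = sample.int(6L, n, replace = TRUE),
    four_to_six = ((sample.int(6L, n, replace = TRUE) - 1L) %% 3L) + 4L,
    sum = Reduce(`+`, lapply(spec$components, roll_n, n))
  )
}

face_value <- function(spec, faces) {
  switch(spec$kind,
    standard_d6 = faces[[1L]],
    four_to_six = ((faces[[1L]] - 1L) %% 3L) + 4L,
    sum = {
      i <- 0L; s <- 0L
      for (comp in spec$components) {
        k <- n_dice(comp)
        s <- s + face_value(comp, faces[(i + 1L):(i + k)])
        i <- i + k
      }
      s
    }
  )
}

#' Analytic mean and minimum of a dice specification
#'
#' @param spec A [dice_spec()].
#' @return `dice_mean()` the expected value; `dice_min()` the smallest
#'   attainable capacity.
#' @export
dice_mean <- function(spec) {
  switch(spec$kind,
    standard_d6 = 3.5,
    four_to_six = 5,
    sum = sum(vapply(spec$components, dice_mean, numeric(1L)))
  )
}

#' @rdname dice_mean
#' @export
dice_min <- function(spec) {
  switch(spec$kind,
    standard_d6 = 1L,
    four_to_six = 4L,
    sum = sum(vapply(spec$components, dice_min, integer(1L)))
  )
}

#' @export
print.dice_spec <- function(x, ...) {
  cat(dice_label(x), "\n", sep = "")
  invisible(x)
}

dice_label <- function(spec) {
  switch(spec$kind,
    standard_d6 = "standard D6",
    four_to_six = "4-6 die (D6 with 1->4, 2->5, 3->6)",
    sum = paste0("sum of [", paste(vapply(spec$components, dice_label,
                                          character(1L)), collapse = " + "), "]")
  )
}
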