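# Architecture registry and plugin mechanism.

.arch_registry <- new.env(parent = emptyenv())

#' Register a segmentation architecture
#'
#' An architecture is a named builder: `build(box_size)` returns the layer
#' spec list understood by the internal CNN engine, and `downsample_factor`
#' states the pooling footprint (`box_size` must be one of its multiples).
#' Registered names can be used with [build_model()].
#'
#' @param name registry key (unique).
#' @param build function `(box_size) -> list of layer specs`.
#' @param downsample_factor total spatial downsampling (1, 2, 4, ...).
#' @param overwrite replace an existing entry of the same name.
#' @return `name`, invisibly.
#' @export
register_architecture <- function(name, build, downsample_factor = 1,
                                  overwrite = FALSE) {
  if (!overwrite && !is.null(.arch_registry[[name]])) {
    stop_fmt("architecture '%s' is already registered", name)
  }
  .arch_registry[[name]] <- list(name = name, build = build,
                                 downsample_factor = downsample_factor)
  invisible(name)
}

#' List registered architecture names
#' @return Character vector of registry keys.
#' @export
list_architectures <- function() sort(ls(.arch_registry))

#' Load architecture plugins from a directory
#'
#' Every `.R` file in `dir` is sourced in an isolated environment and must
#' define an object `architecture`: a list with elements `name`,
#' `downsample_factor` and `build` (same contract as
#' [register_architecture()]). Matching files are auto-registered; this is the
#' extension mechanism for user-supplied network designs.
#'
#' @param dir directory containing plugin files.
#' @return Character vector of registered names, invisibly.
#' @export
load_architecture_plugins <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.R$", full.names = TRUE))
  done <- character()
  for (f in files) {
    env <- new.env(parent = asNamespace("tomoseg"))
    sys.source(f, envir = env)
    a <- env$architecture
    if (is.null(a) || is.null(a$name) || !is.function(a$build)) {
      warn_fmt("plugin %s does not define a valid `architecture`; skipped", f)
      next
    }
    register_architecture(a$name, a$build,
                          downsample_factor = a$downsample_factor %||% 1,
                          overwrite = TRUE)
    done <- c(done, a$name)
  }
  invisible(done)
}

register_builtin_architectures <- function() {
  # shallow 3-conv encoder-decoder, in the spirit of the EMAN2 default net
  register_architecture("eman2", downsample_factor = 2, overwrite = TRUE,
    build = function(box_size) list(
      conv_spec(8, "relu"),
      pool_spec(),
      conv_spec(8, "relu"),
      up_spec(),
      conv_spec(1, "sigmoid")
    ))
  # VGG-style double-conv stack
  register_architecture("vgg", downsample_factor = 2, overwrite = TRUE,
    build = function(box_size) list(
      conv_spec(16, "relu"),
      conv_spec(16, "relu"),
      pool_spec(),
      conv_spec(32, "relu"),
      conv_spec(32, "relu"),
      up_spec(),
      conv_spec(16, "relu"),
      conv_spec(1, "sigmoid")
    ))
  # two-level U-Net with skip connections
  register_architecture("unet", downsample_factor = 4, overwrite = TRUE,
    build = function(box_size) list(
      conv_spec(8, "relu", save = "s1"),
      pool_spec(),
      conv_spec(16, "relu", save = "s2"),
      pool_spec(),
      conv_spec(32, "relu"),
      up_spec(concat = "s2"),
      conv_spec(16, "relu"),
      up_spec(concat = "s1"),
      conv_spec(8, "relu"),
      conv_spec(1, "sigmoid")
    ))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_architectures()
}

#' Build an untrained segmentation model
#'
#' @param arch_name a registered architecture name (see
#'   [list_architectures()]).
#' @param box_size input patch edge in pixels; must be an even multiple of
#'   the architecture's downsampling factor.
#' @param seed optional integer; seeds the weight initialization so two
#'   builds with the same seed are identical.
#' @param feature_name feature the model will segment.
#' @param pixel_size pixel size (Angstrom) of the intended training data.
#' @return An object of class `seg_model`.
#' @export
build_model <- function(arch_name, box_size = 64, seed = NULL,
                        feature_name = "feature", pixel_size = 10) {
  arch <- .arch_registry[[arch_name]]
  if (is.null(arch)) {
    stop_fmt("unknown architecture '%s'; registered: %s", arch_name,
             paste(list_architectures(), collapse = ", "))
  }
  ds <- arch$downsample_factor
  if (box_size < ds || box_size %% ds != 0 || box_size %% 2 != 0) {
    stop_fmt("box_size %d is incompatible with '%s': it must be an even multiple of the downsampling factor %d",
             box_size, arch_name, ds)
  }
  layers <- arch$build(box_size)
  plan <- nn_plan(layers)
  params <- nn_init_params(plan, seed = seed)
  structure(
    list(arch_name = arch_name, box_size = box_size, plan = plan,
         params = params, feature_name = feature_name,
         training_pixel_size = pixel_size, default_threshold = 0.5,
         loss_history = numeric(), trained = FALSE),
    class = "seg_model"
  )
}

#' Count trainable parameters of a model
#'
#' @param model a `seg_model`.
#' @return Integer: total number of trainable scalar weights.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  sum(vapply(model$params, function(p) {
    if (is.null(p)) 0L else length(p$w) + length(p$b)
  }, integer(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> '%s' (%s, %d px): %s parameters, %s\n",
              x$feature_name, x$arch_name, x$box_size,
              format(count_parameters(x), big.mark = ","),
              if (x$trained) sprintf("trained %d epochs (final loss %.4g)",
                                     length(x$loss_history),
                                     utils::tail(x$loss_history, 1))
              else "untrained"))
  invisible(x)
}
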