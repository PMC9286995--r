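# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m) {
  storage.mode(m) <- "double"
  m
}

stop_if_not_mask <- function(m, name = deparse(substitute(m))) {
  if (!is_binary_mask(m))
    stop(sprintf("'%s' must be a binary matrix (values 0/1 or logical)", name),
         call. = FALSE)
  invisible(TRUE)
}

# Largest 4-connected foreground component of a binary mask (empty mask passes
# through unchanged). Used as segmentation post-processing: the LV is a single
# structure.
largest_component <- function(mask) {
  stop_if_not_mask(mask)
  m <- as_mask(mask)
  if (sum(m) == 0) return(m)
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  as_mask(lab == keep)
}

n_components <- function(mask) {
  m <- as_mask(mask)
  if (sum(m) == 0) return(0L)
  max(EBImage::bwlabel(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
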