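#' Resample an arbitrary-resolution dose grid onto the diode lattice
#'
#' Bilinear interpolation of a rectilinear dose grid, given in unwrapped
#' cylinder coordinates, onto the detector's diode positions.  The input
#' grid must cover the full axial extent of the detector; the
#' circumferential axis is treated as periodic.
#'
#' @param values numeric matrix, rows indexed by `z`, columns by `s`.
#' @param z axial coordinates of the rows, mm (strictly monotone).
#' @param s circumferential arc-length coordinates of the columns, mm in
#'   `[0, 2*pi*radius)` (strictly increasing).
#' @param geometry target [detector_geometry()].
#' @return a [detector_map()]; exact at grid nodes that coincide with
#'   diode positions.
#' @export
resample_grid <- function(values, z, s, geometry = detector_geometry()) {
  values <- as.matrix(values)
  if (length(z) != nrow(values) || length(s) != ncol(values))
    stop("z and s must match the grid dimensions")
  if (is.unsorted(s, strictly = TRUE)) stop("s must be strictly increasing")
  if (z[1] < z[length(z)]) {          # store rows with decreasing z
    z <- rev(z); values <- values[rev(seq_len(nrow(values))), , drop = FALSE]
  }
  circ <- 2 * pi * geometry$radius
  if (any(s < 0) || any(s >= circ))
    stop("s must lie in [0, circumference)")
  # periodic closure in s
  s_ext <- c(s, s[1] + circ)
  values <- cbind(values, values[, 1])
  pos <- diode_positions(geometry)
  z_t <- sort(unique(pos$z), decreasing = TRUE)
  s_t <- sort(unique(pos$s))
  if (max(z_t) > max(z) + 1e-9 || min(z_t) < min(z) - 1e-9)
    stop("input grid does not cover the detector's axial extent")
  iz <- findInterval(-z_t, -z, rightmost.closed = TRUE)  # z decreasing
  iz <- pmin(pmax(iz, 1L), length(z) - 1L)
  fz <- (z_t - z[iz]) / (z[iz + 1L] - z[iz])
  is_ <- findInterval(s_t, s_ext, rightmost.closed = TRUE)
  is_ <- pmin(pmax(is_, 1L), length(s_ext) - 1L)
  fs <- (s_t - s_ext[is_]) / (s_ext[is_ + 1L] - s_ext[is_])
  out <- matrix(0, geometry$n_axial, geometry$n_circ)
  for (i in seq_along(z_t)) {
    rowlo <- values[iz[i], ]; rowhi <- values[iz[i] + 1L, ]
    vlo <- rowlo[is_] * (1 - fs) + rowlo[is_ + 1L] * fs
    vhi <- rowhi[is_] * (1 - fs) + rowhi[is_ + 1L] * fs
    out[i, ] <- vlo * (1 - fz[i]) + vhi * fz[i]
  }
  detector_map(out, geometry)
}

#' Turn a plan sample into a model-ready instance
#'
#' Both channels are divided by the single maximum over the two maps
#' jointly (joint normalization: a uniform monitor-unit error keeps its
#' calculated/measured ratio, which per-channel normalization would
#' erase), and the label is one-hot encoded over the five error classes.
#'
#' @param sample a `plan_sample`.
#' @return object of class `model_instance`: `channels` (2 x n_axial x
#'   n_circ array, channel 1 = calculated, channel 2 = measured, values in
#'   `[0, 1]`), `label` (one-hot length 5), `class` (0-4), `plan_id`,
#'   `origin`.
#' @export
normalize_pair <- function(sample) {
  stopifnot(inherits(sample, "plan_sample"))
  m <- max(max(sample$calculated$values), max(sample$measured$values))
  if (m <= 0) stop("all-zero sample cannot be normalized")
  g <- sample$calculated$geometry
  ch <- array(0, dim = c(2, g$n_axial, g$n_circ))
  ch[1, , ] <- sample$calculated$values / m
  ch[2, , ] <- sample$measured$values / m
  onehot <- rep(0, 5)
  onehot[sample$label$code + 1L] <- 1
  structure(list(channels = ch, label = onehot, class = sample$label$code,
                 plan_id = sample$plan_id, origin = sample$plan_id,
                 technique = sample$technique),
            class = "model_instance")
}

# joint circumferential roll of both channels by k columns
roll_instance <- function(inst, k) {
  W <- dim(inst$channels)[3]
  k <- ((k %% W) + W) %% W
  if (k == 0) return(inst)
  ord <- c((W - k + 1):W, 1:(W - k))
  inst$channels <- inst$channels[, , ord, drop = FALSE]
  inst
}

# joint axial flip of both channels
flip_instance <- function(inst) {
  H <- dim(inst$channels)[2]
  inst$channels <- inst$channels[, H:1, , drop = FALSE]
  inst
}

# additive Gaussian perturbation of the measured channel
jitter_instance <- function(inst, sigma) {
  ch <- inst$channels[2, , ]
  ch <- ch + rnorm(length(ch), 0, sigma * max(inst$channels))
  inst$channels[2, , ] <- pmin(pmax(ch, 0), 1)
  inst
}

#' Label-preserving data augmentation
#'
#' Expands the training instances by `factor`: each original is kept and
#' `factor - 1` variants are added, each built from a joint circumferential
#' roll of both channels by 1..5 columns in either direction (a rigid
#' rotation of the whole setup about the cylinder axis), an optional joint
#' axial flip (a superior-inferior mirror; classes pool both error signs,
#' so all five labels survive it), and a small additive Gaussian
#' perturbation (sigma = 0.2% of the maximum) of the measured channel.
#' The default factor of 5 turns 225 training plans into 1125 instances.
#'
#' @param instances list of `model_instance`s.
#' @param factor expansion factor, >= 1.
#' @param seed integer seed.
#' @return list of `factor * length(instances)` instances; variants carry
#'   an `origin` tag `<plan_id>#<k>` and keep `plan_id` (fold assignment is
#'   by plan, so variants never straddle folds).
#' @export
augment <- function(instances, factor = 5L, seed = 1L) {
  if (factor < 1) stop("factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(instances)
  withr_seed(seed, {
    out <- vector("list", factor * length(instances))
    j <- 0L
    for (inst in instances) {
      j <- j + 1L; out[[j]] <- inst
      for (k in seq_len(factor - 1L)) {
        v <- roll_instance(inst, sample(c(-5:-1, 1:5), 1))
        if (runif(1) < 0.5) v <- flip_instance(v)
        v <- jitter_instance(v, 0.002)
        v$origin <- sprintf("%s#%d", inst$plan_id, k)
        j <- j + 1L; out[[j]] <- v
      }
    }
    out
  })
}

#' Stratified train/test split with 5-fold partition
#'
#' Per class, one quarter of the plans go to the test set and the rest to
#' training (45/15 for the default 60 per class); training plans are then
#' dealt round-robin into `n_folds` folds, keeping every fold class
#' balanced.  Fold membership is recorded per plan, so augmented variants
#' of a plan always land in their plan's fold.
#'
#' @param dataset a `qa_dataset` (or any list with `plan_id` and `label`).
#' @param seed integer seed.
#' @param n_folds number of cross-validation folds (default 5).
#' @return object of class `split_plan`: `train_ids`, `test_ids`, `folds`
#'   (list of `n_folds` character vectors of plan ids), `seed`.
#' @export
make_split <- function(dataset, seed = 1L, n_folds = 5L) {
  labs <- dataset_labels(dataset)
  ids <- vapply(dataset, function(s) s$plan_id, "")
  tab <- table(labs)
  if (any(tab < n_folds + 1))
    stop("too few plans per class for the requested fold count")
  withr_seed(seed, {
    train_ids <- character(); test_ids <- character()
    folds <- rep(list(character()), n_folds)
    for (cl in sort(unique(labs))) {
      cls_ids <- sample(ids[labs == cl])
      n_test <- round(length(cls_ids) / 4)
      test_ids <- c(test_ids, cls_ids[seq_len(n_test)])
      tr <- cls_ids[-seq_len(n_test)]
      train_ids <- c(train_ids, tr)
      f <- rep(seq_len(n_folds), length.out = length(tr))
      for (k in seq_len(n_folds))
        folds[[k]] <- c(folds[[k]], tr[f == k])
    }
    structure(list(train_ids = train_ids, test_ids = test_ids,
                   folds = folds, seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test, folds: %s\n",
              length(x$train_ids), length(x$test_ids),
              paste(lengths(x$folds), collapse = "/")))
  invisible(x)
}

#' Fold index of each instance under a split
#' @param instances list of `model_instance`s.
#' @param split a [make_split()] result.
#' @return integer vector; NA for instances not in any training fold.
#' @export
fold_of <- function(instances, split) {
  pid <- vapply(instances, function(i) i$plan_id, "")
  fold <- rep(NA_integer_, length(pid))
  for (k in seq_along(split$folds))
    fold[pid %in% split$folds[[k]]] <- k
  fold
}

instance_labels <- function(instances)
  vapply(instances, function(i) i$class, 0L)

# N x (2*H*W) feature matrix in the row-major layout the CNN kernel expects
instance_features <- function(instances) {
  stopifnot(length(instances) > 0)
  d <- dim(instances[[1]]$channels)
  t(vapply(instances,
           function(i) c(as.vector(t(i$channels[1, , ])),
                         as.vector(t(i$channels[2, , ]))),
           numeric(2 * d[2] * d[3])))
}
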