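# Max-margin convex-polytope clustering: K linear hyperplanes jointly
# separate controls (positive side of every face) from patients, and each
# patient is partitioned by the face it is assigned to. Hyperplanes and
# assignments are estimated by alternating optimization; each face's
# hyperplane is a weighted hinge-loss max-margin classifier in which every
# control carries weight 1/K and a patient carries its assignment indicator.

# Solve one face: weighted linear max-margin classifier via the compiled SMO
# dual solver. `costs` is the per-sample misclassification budget (C * u_i);
# samples with zero cost are excluded.
weighted_linear_svm <- function(X, y, costs, gram = NULL, tol = 1e-4,
                                alpha_init = NULL) {
  stopifnot(length(y) == nrow(X), length(costs) == nrow(X))
  active <- which(costs > 0)
  ya <- y[active]
  if (length(unique(ya)) < 2) abort("both classes must carry positive cost")
  if (is.null(gram)) gram <- tcrossprod(X)
  fit <- wsvm_smo(gram, active, as.numeric(ya), costs[active], tol = tol,
                  alpha_init = alpha_init[active])
  coef_ay <- fit$alpha * ya
  w <- drop(crossprod(X[active, , drop = FALSE], coef_ay))
  list(w = w, b = fit$b, alpha = fit$alpha, active = active,
       objective_dual = fit$objective, iterations = fit$iterations)
}

# patient-to-face assignment given face values f (n_pat x k); ties always
# break toward the lowest face index
assign_rule <- function(f, W, assignment) {
  switch(assignment,
    signed = max.col(f, ties.method = "first"),
    distance = max.col(sweep(f, 2, sqrt(rowSums(W^2)) + 1e-12, "/"),
                       ties.method = "first"),
    hinge = {
      h <- 1 + f
      h[h < 0] <- 0
      max.col(-h, ties.method = "first")
    }
  )
}

# Relabeling-invariant separation objective: each patient pays the hinge of
# its best face. Under the signed rule equivalent optima differ only by a
# face permutation that the assignment cycles through, which inflates the
# as-assigned objective; restarts and plateau detection therefore score how
# well the polytope separates, independent of the labeling the cycle is in.
separation_objective <- function(W, b, Xs, y, patients, C) {
  k <- nrow(W)
  f <- Xs %*% t(W) + matrix(b, nrow(Xs), k, byrow = TRUE)
  hinge_pat <- 1 + f[patients, , drop = FALSE]
  hinge_pat[hinge_pat < 0] <- 0
  hinge_ctrl <- 1 - f[-patients, , drop = FALSE]
  hinge_ctrl[hinge_ctrl < 0] <- 0
  sum(W^2) / 2 + C * (sum(hinge_ctrl) / k +
                        sum(apply(hinge_pat, 1, min)))
}

# primal objective of the full model: sum_j ||w_j||^2/2 + C * weighted hinges
polytope_objective <- function(W, b, Xs, y, S, C, K) {
  f <- Xs %*% t(W) + matrix(b, nrow(Xs), K, byrow = TRUE)
  hinge <- 1 - y * f                    # y recycles down columns
  hinge[hinge < 0] <- 0
  ctrl <- y > 0
  sum(W^2) / 2 +
    C * (sum(hinge[ctrl, , drop = FALSE]) / K +
           sum(S * hinge[!ctrl, , drop = FALSE]))
}

#' Fit a max-margin convex-polytope subtype model
#'
#' Alternates between (i) fitting one weighted hinge-loss max-margin
#' hyperplane per face, with every control weighted 1/K on the positive side
#' and each face's assigned patients weighted 1 on the negative side, and
#' (ii) re-assigning every patient to a face. Iteration stops when the
#' patient partition is unchanged (up to relabeling of faces) or after
#' `max_iter` alternations; the best of `n_init` seeded random restarts by
#' final objective is kept.
#'
#' @param x subject table (with a `diagnosis` column and `roi_` features) or a
#'   numeric matrix of features.
#' @param y ignored when `x` is a subject table; otherwise a vector with
#'   controls coded `+1` and patients `-1` (or `"control"`/`"patient"`).
#' @param k number of faces (subtypes).
#' @param C regularization parameter multiplying the hinge losses.
#' @param max_iter maximum alternations per restart.
#' @param n_init random restarts; best final objective kept.
#' @param assignment patient-to-face rule: `"signed"` (default) assigns to
#'   the face with the largest signed decision value `w.x + b`; `"distance"`
#'   to the Euclidean-closest hyperplane (largest `(w.x+b)/||w||`); `"hinge"`
#'   to the face with the smallest hinge loss (exact block-coordinate
#'   descent, guaranteed monotone objective). Ties break to the lowest face.
#' @param standardize learn per-feature center/scale on the training data and
#'   apply before fitting (stored in the model, applied by `predict()`).
#' @param tol SMO duality-gap tolerance for face fits. Assignments are
#'   argmax decisions over faces and are insensitive to solver slack at this
#'   scale; tighten for applications that consume raw weights.
#' @param seed integer seed driving initial assignments.
#' @param burn_in alternations every restart is run before only the most
#'   promising one (best separation objective) continues to the full budget.
#' @param patience stop a run when its best separation objective has not
#'   improved for this many alternations; the best-visited state is kept.
#' @return A `polysub_polytope` model: weights `W` (k x d), offsets `b`,
#'   patient `labels`, assignment matrix `S`, objective trace, convergence
#'   flag.
#' @export
fit_polytope <- function(x, k, y = NULL, C = 0.25, max_iter = 50, n_init = 5,
                         assignment = c("signed", "distance", "hinge"),
                         standardize = TRUE, tol = 1e-2, seed = 1L,
                         burn_in = 3, patience = 5) {
  assignment <- match.arg(assignment)
  if (is.data.frame(x)) {
    y <- ifelse(x$diagnosis == "control", 1, -1)
    x <- feature_matrix(x)
  } else {
    x <- as.matrix(x)
    if (is.null(y)) abort("y is required when x is a matrix")
    if (is.character(y) || is.factor(y)) {
      y <- ifelse(as.character(y) == "control", 1, -1)
    }
  }
  if (!all(y %in% c(-1, 1))) abort("y must be +1 (control) / -1 (patient)")
  if (length(unique(y)) < 2) abort("both classes must be present")
  patients <- which(y < 0)
  n_pat <- length(patients)
  if (k < 1) abort("k must be >= 1")
  if (k > n_pat) abort("k exceeds the number of patients")

  center <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2, sd) else rep(1, ncol(x))
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  gram <- tcrossprod(Xs)
  d <- ncol(Xs)
  n <- nrow(Xs)

  run_one <- function(init_labels, alpha0 = NULL, budget = max_iter,
                      patience_budget = patience) {
    lab <- init_labels
    W <- matrix(0, k, d)
    b <- numeric(k)
    obj_trace <- numeric(0)
    sep_trace <- numeric(0)
    it <- 0
    costs_base <- ifelse(y > 0, C / k, 0)
    alpha_mem <- alpha0 %||% vector("list", k)  # per-face warm starts
    seen <- character(0)            # canonical partitions already visited
    best <- list(sep = Inf, iter = 0L)
    stopped_by <- "max_iter"
    while (it < budget) {
      it <- it + 1
      # hyperplane step
      for (j in seq_len(k)) {
        costs <- costs_base
        costs[patients[lab == j]] <- C
        fit <- weighted_linear_svm(Xs, y, costs, gram = gram, tol = tol,
                                   alpha_init = alpha_mem[[j]])
        W[j, ] <- fit$w
        b[j] <- fit$b
        am <- numeric(n)
        am[fit$active] <- fit$alpha
        alpha_mem[[j]] <- am
      }
      # assignment step
      f <- Xs[patients, , drop = FALSE] %*% t(W) +
        matrix(b, n_pat, k, byrow = TRUE)
      new_lab <- assign_rule(f, W, assignment)
      # empty-face handling: reseed with the worst-scoring patient
      for (j in which(tabulate(new_lab, k) == 0)) {
        scores <- f[cbind(seq_len(n_pat), new_lab)]
        movable <- which(tabulate(new_lab, k)[new_lab] > 1)
        pick <- movable[which.min(scores[movable])]
        new_lab[pick] <- j
      }
      S <- matrix(0, n_pat, k)
      S[cbind(seq_len(n_pat), new_lab)] <- 1
      obj_trace <- c(obj_trace, polytope_objective(W, b, Xs, y, S, C, k))
      sep <- separation_objective(W, b, Xs, y, patients, C)
      sep_trace <- c(sep_trace, sep)
      if (sep < best$sep) {
        best <- list(sep = sep, W = W, b = b, lab = new_lab, iter = it,
                     alpha = alpha_mem)
      }
      # Stop when (a) the patient partition repeats up to face relabeling:
      # the model is invariant to relabeling, the dynamics are deterministic,
      # and under the signed rule equivalent optima provably cycle through
      # label permutations, so any revisited partition means stationarity;
      # or (b) the best separation objective has not improved for `patience`
      # alternations (on structureless data assignments churn indefinitely
      # without improving the polytope). The best-visited state is kept.
      key <- paste(canonical_labels(new_lab), collapse = ",")
      if (identical(canonical_labels(new_lab), canonical_labels(lab)) ||
          key %in% seen) {
        lab <- new_lab
        stopped_by <- "partition"
        break
      }
      if (it - best$iter >= patience_budget) {
        lab <- new_lab
        stopped_by <- "patience"
        break
      }
      seen <- c(seen, key)
      lab <- new_lab
    }
    list(lab = best$lab, W = best$W, b = best$b, sep_obj = best$sep,
         alpha = best$alpha, obj = obj_trace[length(obj_trace)],
         obj_trace = obj_trace, sep_trace = sep_trace,
         converged = stopped_by != "max_iter", stopped_by = stopped_by,
         n_iter = it)
  }

  # Initialization: seeded random patient prototypes. Each restart draws k
  # patients, takes their deviation from the control centroid as a prototype
  # direction, and assigns every patient to the prototype with the largest
  # projection. Uniformly random assignments are NOT used: a face fitted
  # against a well-mixed patient set admits the degenerate optimum w = 0,
  # b = -1 (all patients on the margin, controls sacrificed), which makes
  # every face identical and collapses the partition; coherent directional
  # seeds avoid that degeneracy (see the methods vignette).
  ctrl_centroid <- colMeans(Xs[y > 0, , drop = FALSE])
  dev <- sweep(Xs[patients, , drop = FALSE], 2, ctrl_centroid)
  inits <- with_seed(seed, {
    lapply(seq_len(n_init), function(i) {
      if (k == 1) return(rep(1L, n_pat))
      # k-means++-style D^2 seeding of the prototypes: spread-out seeds make
      # a restart with one prototype per latent cluster far more likely than
      # uniform draws (which miss a cluster with probability ~(1/2)^(k-1))
      chosen <- sample.int(n_pat, 1)
      while (length(chosen) < k) {
        d2 <- apply(dev[chosen, , drop = FALSE], 1, function(p) {
          rowSums(sweep(dev, 2, p)^2)
        })
        d2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
        d2[chosen] <- 0
        if (sum(d2) <= 0) {
          chosen <- c(chosen, sample.int(n_pat, 1))
        } else {
          chosen <- c(chosen, sample.int(n_pat, 1, prob = d2))
        }
      }
      protos <- dev[chosen, , drop = FALSE]
      proj <- dev %*% t(protos / (sqrt(rowSums(protos^2)) + 1e-12))
      lab <- max.col(proj, ties.method = "first")
      # guarantee every face starts non-empty
      for (j in which(tabulate(lab, k) == 0)) {
        lab[sample.int(n_pat, 1)] <- j
      }
      lab
    })
  })
  # Multi-start: every restart is burned in for a few alternations, then
  # only the most promising run (best separation objective) continues to the
  # full budget, warm-started from its burn-in state.
  burned <- lapply(inits, function(ini) {
    run_one(ini, budget = min(burn_in, max_iter), patience_budget = Inf)
  })
  best <- burned[[which.min(vapply(burned, `[[`, numeric(1), "sep_obj"))]]
  if (max_iter > burn_in) {
    carried <- best$n_iter
    best <- run_one(best$lab, alpha0 = best$alpha,
                    budget = max_iter - burn_in)
    best$n_iter <- best$n_iter + carried
  }

  S <- matrix(0L, n_pat, k)
  S[cbind(seq_len(n_pat), best$lab)] <- 1L
  structure(
    list(k = k, W = best$W, b = best$b, C = C,
         labels = best$lab, S = S, patients = patients,
         center = center, scale = scl, assignment = assignment,
         objective = best$obj, separation_objective = best$sep_obj,
         objective_trace = best$obj_trace,
         separation_trace = best$sep_trace,
         converged = best$converged, stopped_by = best$stopped_by,
         n_iter_run = best$n_iter,
         max_iter = max_iter, n_init = n_init, seed = seed,
         feature_names = colnames(x)),
    class = "polysub_polytope"
  )
}

# decision values of every face for new data, on the model's training scale
face_values <- function(object, newx) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$center)) {
    abort("feature dimension mismatch")
  }
  Xs <- sweep(sweep(newx, 2, object$center), 2, object$scale, "/")
  Xs %*% t(object$W) + matrix(object$b, nrow(Xs), object$k, byrow = TRUE)
}

#' Assign subjects to polytope faces (subtypes)
#'
#' @param object fitted `polysub_polytope`.
#' @param newdata subject table or feature matrix.
#' @param type `"subtype"` (face labels, using the model's assignment rule)
#'   or `"decision"` (the polytope decision score `min_j (w_j.x + b_j)`:
#'   positive = inside the polytope, control-like; negative = patient-like).
#' @param ... unused.
#' @return integer labels or numeric scores.
#' @export
predict.polysub_polytope <- function(object, newdata,
                                     type = c("subtype", "decision"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  f <- face_values(object, newdata)
  if (type == "decision") return(apply(f, 1, min))
  assign_rule(f, object$W, object$assignment)
}

#' Polytope decision score
#'
#' `min_j (w_j . x + b_j)`: positive scores lie inside the polytope
#' (control-like), negative outside (patient-like).
#'
#' @param object fitted `polysub_polytope`.
#' @param newdata subject table or feature matrix.
#' @return numeric vector of signed scores.
#' @export
decision_value <- function(object, newdata) {
  predict(object, newdata, type = "decision")
}

#' @export
print.polysub_polytope <- function(x, ...) {
  cat("<polysub_polytope> k = ", x$k, ", ", length(x$center), " features, ",
      "objective = ", signif(x$objective, 6),
      if (x$converged) ", converged" else ", max_iter reached",
      " (", x$n_iter_run, " iterations)\n", sep = "")
  cat("face sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.polysub_polytope <- function(x, ...) {
  nm <- x$feature_names %||% paste0("x", seq_along(x$center))
  tibble::tibble(
    face = rep(seq_len(x$k), each = length(nm)),
    feature = rep(nm, times = x$k),
    weight = as.vector(t(x$W)),
    offset = rep(x$b, each = length(nm))
  )
}

#' @export
glance.polysub_polytope <- function(x, ...) {
  tibble::tibble(k = x$k, n_patients = length(x$labels),
                 objective = x$objective, converged = x$converged,
                 n_iter = x$n_iter_run, C = x$C)
}

#' Serialize / restore a polytope model as JSON
#'
#' @param model fitted `polysub_polytope`.
#' @param path JSON file path.
#' @export
write_polytope_model <- function(model, path) {
  keep <- c("k", "W", "b", "C", "labels", "center", "scale", "assignment",
            "objective", "converged", "n_iter_run", "seed", "feature_names")
  obj <- model[keep]
  obj$W <- unname(obj$W)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_polytope_model
#' @export
read_polytope_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W <- matrix(as.numeric(obj$W), nrow = obj$k)
  obj$labels <- as.integer(obj$labels)
  lab <- obj$labels
  S <- matrix(0L, length(lab), obj$k)
  S[cbind(seq_along(lab), lab)] <- 1L
  obj$S <- S
  structure(obj, class = "polysub_polytope")
}
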