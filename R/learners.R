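# Base-learner registry. Each entry supplies fit / predict_prob / importance
# with a common signature so ensembles and RFE are learner-agnostic.

learner_registry <- new.env(parent = emptyenv())

register_learner <- function(name, fit, predict_prob, importance) {
  assign(name, list(fit = fit, predict = predict_prob, importance = importance),
         envir = learner_registry)
  invisible(name)
}

get_learner <- function(name) {
  if (!exists(name, envir = learner_registry, inherits = FALSE)) {
    stop("unknown base learner: `", name, "`; see base_learners()", call. = FALSE)
  }
  get(name, envir = learner_registry, inherits = FALSE)
}

#' Registered base learners
#'
#' The ensemble machinery is learner-agnostic; three families are
#' registered:
#' \describe{
#'   \item{`"ridge"`}{Closed-form ridge regression on the 0/1 labels with
#'     predictions clipped to \[0, 1\] (a regularized linear classifier;
#'     the default — fast enough for large ensembles). Hyperparameter:
#'     `lambda` (default 1). Importance: absolute coefficient.}
#'   \item{`"glmnet"`}{Penalized logistic regression via
#'     \pkg{glmnet}. Hyperparameters: `alpha` (default 0), `lambda`
#'     (default 0.01). Importance: absolute coefficient.}
#'   \item{`"xgboost"`}{Gradient-boosted trees via \pkg{xgboost}.
#'     Hyperparameters: `nrounds` (50), `eta` (0.3), `max_depth` (3).
#'     Importance: total gain (0 for unused features).}
#' }
#'
#' @return Character vector of registered learner names.
#' @export
base_learners <- function() sort(ls(envir = learner_registry))

# -- ridge: closed-form regularized linear probability model ------------------
register_learner(
  "ridge",
  fit = function(X, y, params = list()) {
    lambda <- params$lambda %||% 1
    X1 <- cbind(`(Intercept)` = 1, X)
    p <- ncol(X1)
    pen <- diag(lambda, p); pen[1, 1] <- 0        # no penalty on the intercept
    beta <- solve(crossprod(X1) + pen, crossprod(X1, y))
    list(beta = drop(beta))
  },
  predict_prob = function(fit, X) {
    pmin(pmax(drop(cbind(1, X) %*% fit$beta), 0), 1)
  },
  importance = function(fit) abs(fit$beta[-1])
)

# -- glmnet: penalized logistic regression ------------------------------------
register_learner(
  "glmnet",
  fit = function(X, y, params = list()) {
    alpha <- params$alpha %||% 0
    lambda <- params$lambda %||% 0.01
    glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                   lambda = c(lambda * 10, lambda), standardize = FALSE)
  },
  predict_prob = function(fit, X) {
    drop(stats::predict(fit, newx = X, type = "response",
                        s = min(fit$lambda)))
  },
  importance = function(fit) {
    abs(drop(stats::coef(fit, s = min(fit$lambda)))[-1])
  }
)

# -- xgboost: gradient-boosted trees ------------------------------------------
register_learner(
  "xgboost",
  fit = function(X, y, params = list()) {
    bst <- xgboost::xgboost(
      data = X, label = y, verbose = 0, nthread = 1,
      nrounds = params$nrounds %||% 50,
      params = list(objective = "binary:logistic",
                    eta = params$eta %||% 0.3,
                    max_depth = params$max_depth %||% 3)
    )
    list(bst = bst, features = colnames(X), p = ncol(X))
  },
  predict_prob = function(fit, X) stats::predict(fit$bst, X),
  importance = function(fit) {
    imp <- xgboost::xgb.importance(model = fit$bst)
    out <- stats::setNames(rep(0, fit$p),
                           fit$features %||% paste0("f", seq_len(fit$p) - 1))
    if (nrow(imp) > 0) out[imp$Feature] <- imp$Gain
    unname(out)
  }
)
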