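#' Write a model configuration to JSON
#'
#' Serializes muscles (all Hill constants and length polynomials) and plant
#' parameters. Only constant inertia and the built-in gravity forms (zero or
#' `-amplitude * sin(theta)`) can be serialized; models with arbitrary
#' function-valued inertia or gravity must be rebuilt in code.
#'
#' @param model A [one_dof_model()].
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  I0 <- model$inertia(mean(model$theta_range))
  if (!isTRUE(all.equal(model$inertia(model$theta_range[1]), I0)))
    stop("only constant inertia can be serialized")
  thetas <- seq(model$theta_range[1], model$theta_range[2], length.out = 7)
  g <- model$gravity(thetas)
  if (all(g == 0)) {
    grav <- list(type = "none")
  } else {
    amp <- -g[which.max(abs(sin(thetas)))] / sin(thetas[which.max(abs(sin(thetas)))])
    if (!isTRUE(all.equal(as.numeric(g), as.numeric(-amp * sin(thetas)))))
      stop("only zero or sine-form gravity can be serialized")
    grav <- list(type = "sine", amplitude = amp)
  }
  muscles <- lapply(model$muscles, function(mu)
    mu[c("name", "F0max", "length_poly", "l_opt", "l_slack", "pennation",
         "v_max", "fl_width", "fv_shape", "fv_ceiling", "fv_a_dependence")])
  jsonlite::write_json(
    list(name = model$name, inertia = I0, damping = model$damping,
         theta_range = model$theta_range, gravity = grav,
         rep_pos = model$rep_pos, rep_neg = model$rep_neg, muscles = muscles),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model configuration written by [write_model_json()]
#'
#' @param path JSON file path.
#' @return A [one_dof_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  muscles <- lapply(seq_len(nrow(obj$muscles)), function(i) {
    mu <- obj$muscles[i, ]
    muscle_params(name = mu$name, F0max = mu$F0max,
                  length_poly = unlist(mu$length_poly),
                  l_opt = mu$l_opt, l_slack = mu$l_slack,
                  pennation = mu$pennation, v_max = mu$v_max,
                  fl_width = mu$fl_width, fv_shape = mu$fv_shape,
                  fv_ceiling = mu$fv_ceiling,
                  fv_a_dependence = isTRUE(mu$fv_a_dependence),
                  theta_range = as.numeric(obj$theta_range))
  })
  grav <- if (identical(obj$gravity$type, "sine")) {
    amp <- obj$gravity$amplitude
    function(theta) -amp * sin(theta)
  } else 0
  one_dof_model(muscles, inertia = obj$inertia,
                theta_range = as.numeric(obj$theta_range),
                gravity_torque = grav, damping = obj$damping,
                rep_pos = obj$rep_pos, rep_neg = obj$rep_neg, name = obj$name)
}
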