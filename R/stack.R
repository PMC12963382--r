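# Light declarative layer stacks for the generative / inference / pose
# networks: a stack is a list of layer descriptors; stack_init() creates the
# parameter set (with shapes inferred from the input), stack_forward() runs
# it on the tape.  Convolution weights follow the engine layout
# [Cin,kh,kw,Cout] (transposed: [Cout,kh,kw,Cin]).

ly_fc <- function(units) list(kind = "fc", units = units)
ly_conv <- function(maps, k, s, p = 1L) list(kind = "conv", maps = maps, k = k, s = s, p = p)
ly_tconv <- function(maps, k, s, p = 1L, op = 0L)
  list(kind = "tconv", maps = maps, k = k, s = s, p = p, op = op)
ly_bn <- function() list(kind = "bn")
ly_relu <- function() list(kind = "relu")
ly_lrelu <- function(slope = 0.2) list(kind = "lrelu", slope = slope)
ly_sigmoid <- function() list(kind = "sigmoid")
ly_tanh <- function() list(kind = "tanh")
ly_dropout <- function(p) list(kind = "dropout", p = p)
ly_reshape <- function(c, h, w) list(kind = "reshape", c = c, h = h, w = w)
ly_flatten <- function() list(kind = "flatten")

# scheme: "dcgan" = N(0, 0.02) everywhere; "kaiming" = Kaiming with the
# sqrt(2) factor dropped when the layer is not followed by a Re(LU)-family
# nonlinearity
stack_init <- function(layers, in_shape, seed, scheme = c("kaiming", "dcgan")) {
  scheme <- match.arg(scheme)
  params <- list()
  states <- list()
  shape <- in_shape  # c(C,H,W) or scalar F
  followed_by_relu <- function(i) {
    for (j in (i + 1):min(i + 2, length(layers))) {
      if (j > length(layers)) break
      k <- layers[[j]]$kind
      if (k %in% c("relu", "lrelu")) return(TRUE)
      if (!k %in% c("bn")) return(FALSE)
    }
    FALSE
  }
  sd_for <- function(fan, i) {
    if (scheme == "dcgan") 0.02
    else if (followed_by_relu(i)) sqrt(2 / fan) else sqrt(1 / fan)
  }
  with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      nm <- paste0("L", i)
      if (l$kind == "fc") {
        fan <- prod(shape)
        params[[paste0(nm, "_W")]] <- ag_param(rnorm_arr(c(fan, l$units), sd_for(fan, i)))
        params[[paste0(nm, "_b")]] <- ag_param(numeric(l$units))
        shape <- l$units
      } else if (l$kind == "conv") {
        fan <- shape[1] * l$k^2
        params[[paste0(nm, "_W")]] <- ag_param(
          rnorm_arr(c(shape[1], l$k, l$k, l$maps), sd_for(fan, i)))
        params[[paste0(nm, "_b")]] <- ag_param(numeric(l$maps))
        shape <- c(l$maps, (shape[2] + 2 * l$p - l$k) %/% l$s + 1,
                   (shape[3] + 2 * l$p - l$k) %/% l$s + 1)
      } else if (l$kind == "tconv") {
        fan <- shape[1] * l$k^2
        params[[paste0(nm, "_W")]] <- ag_param(
          rnorm_arr(c(l$maps, l$k, l$k, shape[1]), sd_for(fan, i)))
        params[[paste0(nm, "_b")]] <- ag_param(numeric(l$maps))
        shape <- c(l$maps, (shape[2] - 1) * l$s - 2 * l$p + l$k + l$op,
                   (shape[3] - 1) * l$s - 2 * l$p + l$k + l$op)
      } else if (l$kind == "bn") {
        nunit <- shape[1]
        g0 <- if (scheme == "dcgan") 1 + stats::rnorm(nunit, 0, 0.02) else rep(1, nunit)
        params[[paste0(nm, "_g")]] <- ag_param(g0)
        params[[paste0(nm, "_b")]] <- ag_param(numeric(nunit))
        states[[nm]] <- new.env(parent = emptyenv())
      } else if (l$kind == "reshape") {
        shape <- c(l$c, l$h, l$w)
      } else if (l$kind == "flatten") {
        shape <- prod(shape)
      }
    }
  })
  list(params = params, states = states, layers = layers,
       in_shape = in_shape, out_shape = shape)
}

stack_forward <- function(st, x, tape, training = FALSE) {
  p <- st$params
  cur <- x
  n <- dim(x$val)[length(dim(x$val))]
  for (i in seq_along(st$layers)) {
    l <- st$layers[[i]]
    nm <- paste0("L", i)
    cur <- switch(
      l$kind,
      fc = {
        if (length(dim(cur$val)) > 2)
          cur <- ag_reshape(cur, c(prod(dim(cur$val)[-length(dim(cur$val))]), n), tape)
        ag_fc(cur, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]], tape)
      },
      conv = ag_conv2d(cur, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                       stride = l$s, pad = l$p, tape = tape),
      tconv = ag_conv_transpose2d(cur, p[[paste0(nm, "_W")]],
                                  p[[paste0(nm, "_b")]], stride = l$s,
                                  pad = l$p, output_padding = l$op, tape = tape),
      bn = ag_batchnorm(cur, p[[paste0(nm, "_g")]], p[[paste0(nm, "_b")]],
                        st$states[[nm]], training, tape),
      relu = ag_relu(cur, tape),
      lrelu = ag_lrelu(cur, l$slope, tape),
      sigmoid = ag_sigmoid(cur, tape),
      tanh = ag_tanh(cur, tape),
      dropout = ag_dropout(cur, l$p, training, tape),
      reshape = ag_reshape(cur, c(l$c, l$h, l$w, n), tape),
      flatten = ag_reshape(cur, c(prod(dim(cur$val)[-length(dim(cur$val))]), n), tape)
    )
  }
  cur
}

stack_param_list <- function(st, prefix = "") {
  out <- st$params
  names(out) <- paste0(prefix, names(out))
  out
}
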