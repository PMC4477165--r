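# Fixed-step block-graph executor. Blocks fire once per step in a
# topological order computed over the non-feedback wires; wires flagged as
# feedback carry a one-step delay register with a declared initial value,
# matching sample-and-hold controller semantics (no algebraic loops are
# solved).

#' Define a processing block
#'
#' A block exposes named input and output ports and a step function
#' `step(block, state, inputs, t, dt)` returning
#' `list(outputs = <named list>, state = <state>)`. Stochastic blocks may
#' supply `setup(block, n_steps, dt, seed)` returning a state initialized
#' with pre-generated noise from the block's child stream.
#'
#' @param name unique block name.
#' @param kind short kind tag (informational).
#' @param inputs,outputs character vectors of port names.
#' @param step the step function.
#' @param init_state initial state (any list), or NULL.
#' @param setup optional function building the initial state at run start.
#' @param constants named list supplying fixed values for unwired inputs.
#' @return list of class `"block"`.
#' @export
block <- function(name, kind, inputs = character(0), outputs, step,
                  init_state = NULL, setup = NULL, constants = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(step))
  structure(list(name = name, kind = kind, inputs = inputs, outputs = outputs,
                 step = step, init_state = init_state, setup = setup,
                 constants = constants),
            class = "block")
}

#' Constant source block
#' @param name block name. @param value emitted on port `"out"` every step.
#' @export
block_constant <- function(name, value) {
  block(name, "constant", outputs = "out",
        step = function(blk, state, inputs, t, dt) {
          list(outputs = list(out = value), state = state)
        })
}

#' Gain block: `out = k * in`
#' @param name block name. @param k gain.
#' @export
block_gain <- function(name, k) {
  block(name, "gain", inputs = "in", outputs = "out",
        step = function(blk, state, inputs, t, dt) {
          list(outputs = list(out = k * inputs$`in`), state = state)
        })
}

#' Sum block: `out = a + b`
#' @param name block name.
#' @export
block_sum <- function(name) {
  block(name, "sum", inputs = c("a", "b"), outputs = "out",
        step = function(blk, state, inputs, t, dt) {
          list(outputs = list(out = inputs$a + inputs$b), state = state)
        })
}

#' Stateless function block
#' @param name block name. @param f function of the named input list (and
#'   optionally `t`) returning a named list of outputs.
#' @param inputs,outputs port names.
#' @export
block_function <- function(name, f, inputs, outputs) {
  block(name, "function", inputs = inputs, outputs = outputs,
        step = function(blk, state, inputs_, t, dt) {
          out <- if ("t" %in% names(formals(f))) f(inputs_, t = t) else f(inputs_)
          list(outputs = out, state = state)
        })
}

#' Waveform source block emitting a pre-compiled trace sample-by-sample
#' @param name block name. @param spec a [waveform_spec()].
#' @export
block_waveform <- function(name, spec) {
  block(name, "waveform", outputs = "out",
        setup = function(blk, n, dt, seed) {
          tr <- compile_waveform(spec, dt, seed)
          v <- tr$values
          if (length(v) < n) v <- c(v, rep(v[length(v)] %||% 0, n - length(v)))
          list(values = v, i = 0L)
        },
        step = function(blk, state, inputs, t, dt) {
          state$i <- state$i + 1L
          list(outputs = list(out = state$values[[state$i]]), state = state)
        })
}

#' Ornstein-Uhlenbeck conductance source block
#' @param name block name (also keys the child noise stream).
#' @param params an [ou_params()] object.
#' @export
block_ou <- function(name, params) {
  block(name, "ou_source", outputs = "out",
        setup = function(blk, n, dt, seed) {
          list(noise = child_normals(seed, name, n), G = params$G_bar, i = 0L)
        },
        step = function(blk, state, inputs, t, dt) {
          state$i <- state$i + 1L
          state$G <- ou_step(params, state$G, dt, state$noise[[state$i]])
          list(outputs = list(out = state$G), state = state)
        })
}

#' Point-neuron block
#'
#' Input port `"I"` (A); output ports `"V"` (V) and `"spike"` (0/1).
#' @param name block name. @param params a `"neuron_params"` object.
#' @param V0 initial potential.
#' @export
block_neuron <- function(name, params, V0 = params$E_L) {
  block(name, "neuron", inputs = "I", outputs = c("V", "spike"),
        init_state = init_neuron_state(params, V0),
        step = function(blk, state, inputs, t, dt) {
          r <- step_point_neuron(params, state, inputs$I, dt, t)
          list(outputs = list(V = r$state$V, spike = as.numeric(r$spike)),
               state = r$state)
        })
}

parse_port <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("port reference '", x, "' is not 'block:port'")
  list(block = parts[[1]], port = parts[[2]])
}

#' Wire two ports
#' @param from,to `"block:port"` references.
#' @param feedback flag the wire as carrying a one-step delay.
#' @param init initial value of the delay register (feedback wires only).
#' @export
wire <- function(from, to, feedback = FALSE, init = 0) {
  list(from = from, to = to, feedback = isTRUE(feedback), init = init)
}

#' Build and validate a block graph
#'
#' Checks that every referenced block and port exists, that each input port
#' has exactly one incoming wire or a declared constant, and that the graph
#' with feedback wires removed is acyclic (cycles are rejected, never broken
#' by silently inserting delays). Returns the graph with a topological
#' execution order.
#'
#' @param blocks list of [block()] objects.
#' @param wires list of [wire()] objects.
#' @return list of class `"block_graph"`.
#' @export
build_graph <- function(blocks, wires = list()) {
  names(blocks) <- vapply(blocks, function(b) b$name, "")
  if (anyDuplicated(names(blocks))) stop("duplicate block names")
  for (w in wires) {
    f <- parse_port(w$from); t <- parse_port(w$to)
    if (!f$block %in% names(blocks)) stop("unknown block '", f$block, "'")
    if (!t$block %in% names(blocks)) stop("unknown block '", t$block, "'")
    if (!f$port %in% blocks[[f$block]]$outputs)
      stop("dangling port: '", w$from, "' is not an output of '", f$block, "'")
    if (!t$port %in% blocks[[t$block]]$inputs)
      stop("dangling port: '", w$to, "' is not an input of '", t$block, "'")
  }
  # every input port: exactly one wire or a constant
  for (b in blocks) {
    for (p in b$inputs) {
      ref <- paste0(b$name, ":", p)
      k <- sum(vapply(wires, function(w) w$to == ref, TRUE))
      if (k > 1L) stop("input port '", ref, "' has ", k, " incoming wires")
      if (k == 0L && !p %in% names(b$constants))
        stop("input port '", ref, "' is unwired and has no declared constant")
    }
  }
  # topological order over non-feedback wires (Kahn)
  fwd <- Filter(function(w) !w$feedback, wires)
  deps <- lapply(names(blocks), function(nm) {
    unique(vapply(Filter(function(w) parse_port(w$to)$block == nm, fwd),
                  function(w) parse_port(w$from)$block, ""))
  })
  names(deps) <- names(blocks)
  order <- character(0)
  remaining <- names(blocks)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      !any(deps[[nm]] %in% remaining)
    }, TRUE)]
    if (!length(ready))
      stop("cycle not broken by any feedback edge among blocks: ",
           paste(remaining, collapse = ", "))
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(blocks = blocks, wires = wires, order = order),
            class = "block_graph")
}

#' @export
print.block_graph <- function(x, ...) {
  cat(sprintf("<block_graph> %d blocks, %d wires (%d feedback)\n",
              length(x$blocks), length(x$wires),
              sum(vapply(x$wires, function(w) w$feedback, TRUE))))
  cat("execution order:", paste(x$order, collapse = " -> "), "\n")
  invisible(x)
}

#' Run a block graph at a fixed step
#'
#' Executes `floor(duration/dt)` steps. Within a step, blocks fire in the
#' topological order; feedback wires read the register written on the
#' previous step. Identical `(graph, duration, dt, seed)` runs produce
#' identical logs. Model time is derived as `t = (n-1) * dt`, never
#' accumulated.
#'
#' @param graph a [build_graph()] result.
#' @param duration run length (s). @param dt step (s).
#' @param seed root integer seed; stochastic blocks derive child streams.
#' @param log character vector of `"block:port"` channels to record.
#' @param delay_steps feedback register depth (default 1; exposed so tests
#'   can verify that the delay is actually honored).
#' @return named list of [trace()] objects, one per logged channel.
#' @export
run_fixed_step <- function(graph, duration, dt, seed = 0L, log = character(0),
                           delay_steps = 1L) {
  stopifnot(inherits(graph, "block_graph"), duration > 0, dt > 0,
            delay_steps >= 1L)
  n <- n_steps(duration, dt)
  blocks <- graph$blocks
  states <- lapply(blocks, function(b) {
    if (!is.null(b$setup)) b$setup(b, n, dt, seed) else b$init_state
  })
  fb <- Filter(function(w) w$feedback, graph$wires)
  # each feedback wire holds a FIFO of depth delay_steps
  registers <- lapply(fb, function(w) rep(w$init, delay_steps))
  fb_to <- vapply(fb, function(w) w$to, "")
  fwd <- Filter(function(w) !w$feedback, graph$wires)
  fwd_to <- vapply(fwd, function(w) w$to, "")
  logs <- matrix(NA_real_, nrow = n, ncol = length(log))
  colnames(logs) <- log
  log_src <- lapply(log, parse_port)
  outputs <- list()
  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    for (nm in graph$order) {
      b <- blocks[[nm]]
      ins <- b$constants
      for (p in b$inputs) {
        ref <- paste0(nm, ":", p)
        j <- match(ref, fwd_to)
        if (!is.na(j)) {
          src <- parse_port(fwd[[j]]$from)
          ins[[p]] <- outputs[[src$block]][[src$port]]
        } else {
          k <- match(ref, fb_to)
          if (!is.na(k)) ins[[p]] <- registers[[k]][[delay_steps]]
        }
      }
      r <- b$step(b, states[[nm]], ins, t, dt)
      vals <- unlist(r$outputs, use.names = FALSE)
      if (any(!is.finite(vals)))
        stop("non-finite value in block '", nm, "' at step ", i)
      outputs[[nm]] <- r$outputs
      states[[nm]] <- r$state
    }
    if (length(fb)) {
      for (k in seq_along(fb)) {
        src <- parse_port(fb[[k]]$from)
        registers[[k]] <- c(outputs[[src$block]][[src$port]],
                            registers[[k]][-delay_steps])
      }
    }
    if (length(log)) {
      for (j in seq_along(log)) {
        logs[i, j] <- outputs[[log_src[[j]]$block]][[log_src[[j]]$port]]
      }
    }
  }
  stats::setNames(lapply(seq_along(log), function(j) {
    trace(logs[, j], dt = dt, unit = "1", t0 = 0)
  }), log)
}

#' Triggered segment container
#'
#' @param trigger_time trigger time (s). @param pre_window,post_window
#'   window extents (s, nonnegative). @param traces named list of [trace()]
#'   objects spanning exactly `[trigger - pre, trigger + post]`.
#' @return list of class `"triggered_segment"`.
#' @export
triggered_segment <- function(trigger_time, pre_window, post_window, traces) {
  stopifnot(pre_window >= 0, post_window >= 0)
  structure(list(trigger_time = trigger_time, pre_window = pre_window,
                 post_window = post_window, traces = traces),
            class = "triggered_segment")
}

#' Cut triggered logging windows out of continuous channels
#'
#' One segment per trigger that fits entirely inside the recording; triggers
#' too close to either edge are skipped and reported in the `"skipped"`
#' attribute rather than failing the run. Samples are copied, so later
#' mutation of the source traces does not alter the segments. Each segment
#' spans `[trigger - pre_window, trigger + post_window]` inclusive of both
#' endpoints (`(pre + post)/dt + 1` samples).
#'
#' @param trigger_times numeric trigger times (s).
#' @param channels named list of [trace()] objects sharing `dt`.
#' @param pre_window,post_window window extents (s).
#' @return list of [triggered_segment()]s, ordered by trigger time, with
#'   attribute `"skipped"` holding the skipped trigger times.
#' @export
segment_logger <- function(trigger_times, channels, pre_window = 10e-3,
                           post_window = 500e-3) {
  stopifnot(pre_window >= 0, post_window >= 0, length(channels) > 0)
  dts <- vapply(channels, function(x) x$dt, 0)
  if (max(dts) - min(dts) > 1e-12) stop("channels must share dt")
  dt <- dts[[1]]
  t0 <- channels[[1]]$t0
  n <- length(channels[[1]])
  npre <- as.integer(round(pre_window / dt))
  npost <- as.integer(round(post_window / dt))
  trigger_times <- sort(trigger_times)
  segs <- list()
  skipped <- numeric(0)
  for (tt in trigger_times) {
    idx <- as.integer(round((tt - t0) / dt)) + 1L
    lo <- idx - npre
    hi <- idx + npost
    if (lo < 1L || hi > n) {
      skipped <- c(skipped, tt)
      next
    }
    traces <- lapply(channels, function(ch) {
      trace(ch$values[lo:hi], dt = dt, unit = ch$unit, t0 = tt - pre_window)
    })
    segs[[length(segs) + 1L]] <-
      triggered_segment(tt, pre_window, post_window, traces)
  }
  if (length(skipped))
    message(length(skipped), " trigger(s) too close to the stream edge; skipped")
  attr(segs, "skipped") <- skipped
  segs
}

#' Write triggered segments to per-trigger text files
#' @param segments list of [triggered_segment()]s.
#' @param dir output directory; files are named `segment_<index>.tsv`.
#' @return character vector of file paths, invisibly.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(segments), function(i) {
    f <- file.path(dir, sprintf("segment_%04d.tsv", i))
    write_log_store(segments[[i]]$traces, f)
    f
  }, "")
  invisible(paths)
}
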