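# Helpers to build tiny networks in code.
chain_spec <- function() {
  network_spec(
    nodes = data.frame(name = c("A", "B"),
                       role = c("input", "output_tf"),
                       h = 10, gamma = 1),
    edges = data.frame(source = "A", sign = "+", target = "B", weight = 1))
}

cascade_spec <- function() {
  network_spec(
    nodes = data.frame(name = c("A", "B", "C"),
                       role = c("input", "internal", "output_tf"),
                       h = 10, gamma = 1),
    edges = data.frame(source = c("A", "B"), sign = c("+", "-"),
                       target = c("B", "C"), weight = 1))
}

random_ff_spec <- function(seed, n_in = 2, n_mid = 2, n_out = 2) {
  set.seed(seed)
  nm <- c(paste0("I", 1:n_in), paste0("M", 1:n_mid), paste0("O", 1:n_out))
  role <- c(rep("input", n_in), rep("internal", n_mid), rep("output_tf", n_out))
  edges <- NULL
  for (tgt in which(role != "input")) {
    src <- sample(seq_len(tgt - 1), sample(1:min(2, tgt - 1), 1))
    edges <- rbind(edges, data.frame(
      source = nm[src], sign = sample(c("+", "-"), length(src), TRUE),
      target = nm[tgt], weight = runif(length(src), 0.5, 2)))
  }
  network_spec(data.frame(name = nm, role = role,
                          h = sample(c(5, 10, 20), length(nm), TRUE),
                          gamma = runif(length(nm), 1, 2)), edges)
}

test_that("SIF parsing infers roles, applies sidecars and flags bad lines", {
  p <- file.path(tempdir(), "net.sif")
  writeLines(c("A\t+\tB", "B\t-\tC"), p)
  spec <- parse_network(p)
  expect_equal(nrow(spec$nodes), 3)
  expect_equal(spec$nodes$role[spec$nodes$name == "A"], "input")
  expect_equal(spec$nodes$role[spec$nodes$name == "C"], "output_tf")
  expect_equal(nrow(spec$edges), 2)

  writeLines(c("A\t+\tB", "B\t?\tC"), p)
  expect_error(parse_network(p), "line 2")
  writeLines("A\t+\tB\tnot_a_number", p)
  expect_error(parse_network(p), "weight")

  writeLines("A\t+\tB", p)
  side <- file.path(tempdir(), "roles.yaml")
  yaml::write_yaml(list(roles = list(Z = "input")), side)
  expect_error(parse_network(p, side), "undeclared node")
  # declaring a regulated node as input violates the no-incoming rule
  yaml::write_yaml(list(roles = list(B = "input")), side)
  expect_error(parse_network(p, side), class = "oastratify_config_error")
})

test_that("the bundled example network parses with 8 inputs and 8 TF outputs", {
  spec <- parse_network(example_network_path("sif"),
                        example_network_path("roles"))
  expect_gte(nrow(spec$nodes), 16)
  expect_setequal(spec$nodes$name[spec$nodes$role == "input"],
                  c("IL8", "IL6", "IL4", "TNFa", "IL18", "IFNg", "IL17", "VEGF"))
  expect_setequal(spec$nodes$name[spec$nodes$role == "output_tf"],
                  c("CITED2", "CREB", "RUNX2", "FOXO", "SOX9", "HIF2A",
                    "NFKB", "AP1"))
})

test_that("analyte rescaling is min-max with the constant-column convention", {
  tab <- data.frame(IL6 = c(2, 4, 6), IL8 = c(5, 5, 5))
  rownames(tab) <- paste0("P", 1:3)
  expect_warning(ri <- rescale_inputs(tab, c(IL6 = "A", IL8 = "B")),
                 "constant")
  expect_equal(unname(sapply(ri, function(r) r$values["A"])), c(0, 0.5, 1))
  expect_equal(unname(sapply(ri, function(r) r$values["B"])), rep(0.5, 3))

  set.seed(8)
  for (i in 1:20) {
    tab <- data.frame(x = rlnorm(10), y = rlnorm(10))
    ri <- rescale_inputs(tab, c(x = "X", y = "Y"))
    vals <- do.call(rbind, lapply(ri, `[[`, "values"))
    expect_true(all(vals >= 0 & vals <= 1))
  }
  expect_error(rescale_inputs(data.frame(x = 1:3), c(x = "B"),
                              spec = chain_spec()),
               class = "oastratify_config_error")  # input A unmapped
})

test_that("the normalized sigmoid hits its anchor points", {
  for (h in c(1, 5, 10, 50)) {
    expect_equal(mendoza_sigmoid(0, h), 0, tolerance = 1e-12)
    expect_equal(mendoza_sigmoid(1, h), 1, tolerance = 1e-12)
    expect_equal(mendoza_sigmoid(0.5, h), 0.5, tolerance = 1e-12)
    om <- seq(0, 1, by = 0.01)
    expect_true(all(diff(mendoza_sigmoid(om, h)) > 0))  # strictly increasing
  }
  expect_equal(node_rate(0, 0, 10, 1), 0)
  expect_equal(node_rate(1, 1, 7, 1), 0)
  expect_equal(node_rate(0.5, 0, 10, 1), 0.5)
})

test_that("regulatory drive normalizes to the unit interval", {
  sp <- network_spec(
    nodes = data.frame(name = c("A", "I", "T"),
                       role = c("input", "input", "output_tf"),
                       h = 10, gamma = 1),
    edges = data.frame(source = c("A", "I"), sign = c("+", "-"),
                       target = c("T", "T"), weight = 1))
  expect_equal(regulatory_input("T", c(A = 1, I = 0), sp), 1)
  expect_equal(regulatory_input("T", c(A = 0, I = 0), sp), 0)
  expect_equal(regulatory_input("T", c(A = 1, I = 1), sp), 0)
  expect_error(regulatory_input("A", c(A = 1), sp),
               class = "oastratify_config_error")
})

test_that("a clamped input chain reaches the input's fixed point", {
  sp <- chain_spec()
  s1 <- simulate_to_steady_state(sp, list(patient_id = "p", values = c(A = 1)),
                                 x0 = 0)
  expect_true(s1$converged)
  expect_equal(unname(s1$activations["B"]), 1, tolerance = 1e-4)
  s0 <- simulate_to_steady_state(sp, list(patient_id = "p", values = c(A = 0)),
                                 x0 = 0.9)
  expect_true(s0$converged)
  expect_equal(unname(s0$activations["B"]), 0, tolerance = 1e-4)
})

test_that("acyclic cascades reach an x0-independent steady state", {
  sp <- cascade_spec()
  tol <- 1e-6
  ri <- list(patient_id = "p", values = c(A = 0.7))
  lo <- simulate_to_steady_state(sp, ri, x0 = 0, tol = tol)
  hi <- simulate_to_steady_state(sp, ri, x0 = 1, tol = tol)
  expect_true(lo$converged && hi$converged)
  expect_lt(max(abs(lo$activations - hi$activations)), 10 * tol)
})

test_that("trajectories stay inside the unit hypercube for random networks", {
  for (s in 1:25) {
    sp <- random_ff_spec(s)
    set.seed(s + 1000)
    iv <- runif(sum(sp$nodes$role == "input"))
    names(iv) <- sp$nodes$name[sp$nodes$role == "input"]
    st <- simulate_to_steady_state(sp, list(patient_id = "p", values = iv),
                                   x0 = runif(1))
    expect_true(all(st$activations >= 0 & st$activations <= 1))
    expect_true(st$converged)
  }
})

test_that("batch simulation is deterministic, order-preserving and monotone", {
  spec <- parse_network(example_network_path("sif"),
                        example_network_path("roles"))
  set.seed(12)
  inputs <- lapply(1:5, function(i) {
    v <- runif(8); names(v) <- spec$nodes$name[spec$nodes$role == "input"]
    list(patient_id = paste0("P", i), values = v)
  })
  inputs[[2]] <- modifyList(inputs[[1]], list(patient_id = "P2"))
  tf <- batch_simulate(spec, inputs)
  expect_equal(nrow(tf$data), 5)
  expect_equal(ncol(tf$data), 9)   # id + 8 TFs
  expect_equal(unlist(tf$data[1, -1]), unlist(tf$data[2, -1]),
               ignore_attr = TRUE)

  perm <- c(3, 1, 5, 2, 4)
  tf2 <- batch_simulate(spec, inputs[perm])
  expect_equal(tf2$data, tf$data[perm, ], ignore_attr = TRUE)

  # raising an activating input never lowers its direct target
  base <- inputs[[3]]
  hi <- base; hi$values["IL6"] <- min(1, base$values["IL6"] + 0.4)
  r1 <- simulate_to_steady_state(spec, base)
  r2 <- simulate_to_steady_state(spec, hi)
  expect_gte(r2$activations["NFKB"], r1$activations["NFKB"] - 1e-6)
})

test_that("inputs-as-initial-condition mode lets inputs decay", {
  sp <- chain_spec()
  st <- simulate_to_steady_state(sp, list(patient_id = "p", values = c(A = 1)),
                                 x0 = 0, inputs_as_ic = TRUE)
  expect_true(st$converged)
  expect_lt(unname(st$activations["A"]), 1e-3)   # decayed
  expect_lt(unname(st$activations["B"]), 0.2)    # loses its drive
})
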