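# Stored search behind the mutual_excitation_oscillator fixture.
#
# Deliberately independent of the package: the vector field, equilibrium
# construction and stability scan are written out by hand here, so the
# fixture's frozen expectations (instability at zero input, the amplitude
# window containing the stability flip, and the limit-cycle period) come
# from a second route, not from the code they are used to test.
#
# Run from the repository root:  Rscript tools/search_oscillator.R

G <- 500          # pS, each synapse of the E-I pair
beta <- 0.125 * 40
Cm <- 1; Gc <- 10; Ecell <- -35; ar <- 1; ad <- 5
Ej <- c(0, -45)   # neuron 1 excitatory, neuron 2 inhibitory
syn <- matrix(c(0, G, G, 0), 2, 2, byrow = TRUE)  # [i,j] = onto i from j
# note: syn[1,2]=G (inhibitory feedback onto 1), syn[2,1]=G (drive onto 2)

sig <- function(x) 1 / (1 + exp(-x))
field <- function(y, Vth, I) {
  V <- y[1:2]; s <- y[3:4]
  dV <- (-Gc * (V - Ecell) - (syn %*% s) * V + syn %*% (s * Ej) + I) / Cm
  phi <- sig(beta * (V - Vth))
  c(dV, ar * phi * (1 - s) - ad * s)
}

# standard equilibrium: phi = 1/2 => s* = (ar/2)/(ar/2 + ad); linear solve
s_star <- (ar / 2) / (ar / 2 + ad)
A <- diag(Gc + s_star * rowSums(syn)) # no gap junctions in this fixture
b <- Gc * Ecell + s_star * (syn %*% Ej)
Veq <- solve(A, b)[, 1]
Vth <- Veq
cat("Veq:", round(Veq, 4), "\n")

lead_at <- function(amp) {
  I <- c(amp, 0)
  # damped fixed-point iteration via optimisation of |field|^2
  fit <- optim(c(Veq, s_star, s_star), function(y) sum(field(y, Vth, I)^2),
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-16))
  y0 <- fit$par
  h <- 1e-6
  J <- sapply(1:4, function(k) {
    e <- numeric(4); e[k] <- h
    (field(y0 + e, Vth, I) - field(y0 - e, Vth, I)) / (2 * h)
  })
  max(Re(eigen(J, only.values = TRUE)$values))
}

cat("leading real part at amp 0:  ", lead_at(0), "\n")
cat("leading real part at amp 100:", lead_at(100), "\n")
scan <- sapply(seq(0, 100, by = 5), lead_at)
flip <- which(scan < 0)[1]
cat("flip between amplitudes", seq(0, 100, by = 5)[flip - 1], "and",
    seq(0, 100, by = 5)[flip], "\n")

# limit-cycle period at zero input: integrate, then zero-crossing intervals
library(deSolve)
out <- lsoda(c(Veq + c(0.5, -0.5), s_star, s_star),
             seq(0, 60, by = 0.002),
             function(t, y, p) list(field(y, Vth, c(0, 0))),
             parms = NULL, rtol = 1e-10, atol = 1e-12)
v1 <- out[out[, 1] >= 40, 2]
tt <- out[out[, 1] >= 40, 1]
x <- v1 - mean(v1)
up <- which(x[-1] > 0 & x[-length(x)] <= 0)
period <- mean(diff(tt[up]))
cat("limit-cycle period (zero-crossing mean):", period, "s\n")
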