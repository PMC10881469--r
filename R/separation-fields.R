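## Device geometry and field solvers for the 2D microfluidic DEP sorter:
## a quasi-static Laplace solve for the electrode potential, the derived
## field-intensity gradient, and a fully developed laminar flow profile.

#' @importFrom Matrix sparseMatrix solve
NULL

#' Scalar field on a rectangular grid
#' @slot x,y node coordinates (m), strictly increasing
#' @slot values matrix, \code{length(x)} x \code{length(y)}
#' @name ScalarField2D-class
#' @exportClass ScalarField2D
setClass("ScalarField2D",
    representation(x = "numeric", y = "numeric", values = "matrix"))

#' Vector field on a rectangular grid
#' @slot x,y node coordinates (m)
#' @slot vx,vy component matrices, \code{length(x)} x \code{length(y)}
#' @name VectorField2D-class
#' @exportClass VectorField2D
setClass("VectorField2D",
    representation(x = "numeric", y = "numeric", vx = "matrix", vy = "matrix"))

setMethod("show", "ScalarField2D", function(object) {
    cat("ScalarField2D:", length(object@x), "x", length(object@y),
        "grid, range", sprintf("%.3g .. %.3g", min(object@values),
        max(object@values)), "\n")
})

setMethod("show", "VectorField2D", function(object) {
    cat("VectorField2D:", length(object@x), "x", length(object@y), "grid\n")
})

#' Geometry of the DEP separation channel
#'
#' A 2D plan view of the central separation channel.  The axial coordinate
#' x runs from inlet (0) to outlet (\code{length}); the lateral coordinate y
#' from the left wall (0) to the right wall (\code{width}).  Electrodes sit
#' on the channel floor and appear in the plan view as fixed-potential
#' strips: each element of \code{electrodes} is a list with \code{role}
#' ("phase" or "neutral"), polyline coordinates \code{x}, \code{y}, and a
#' \code{halfWidth} (m).  Particles enter within the right-side lateral band
#' \code{inletBand} (fractions of the width, modelling the sheath-flow
#' focusing of the upstream junction) and are assigned to the left or right
#' outlet according to the lateral \code{split} coordinate at the channel
#' end.
#'
#' @slot length,width channel dimensions (m)
#' @slot electrodes list of electrode segments (see description)
#' @slot inletBand length-2 numeric, entry band as fractions of width
#' @slot split lateral outlet-split coordinate (m), 0 < split < width
#' @name DeviceGeometry-class
#' @exportClass DeviceGeometry
setClass("DeviceGeometry",
    representation(length = "numeric", width = "numeric",
        electrodes = "list", inletBand = "numeric", split = "numeric"))

setValidity("DeviceGeometry", function(object) {
    msg <- character()
    if (!(object@length > 0 && object@width > 0))
        msg <- c(msg, "length and width must be positive")
    if (!(object@split > 0 && object@split < object@width))
        msg <- c(msg, "split must lie strictly inside (0, width)")
    if (length(object@inletBand) != 2L || object@inletBand[1] < 0 ||
        object@inletBand[2] > 1 || object@inletBand[1] >= object@inletBand[2])
        msg <- c(msg, "inletBand must be increasing fractions within [0, 1]")
    for (e in object@electrodes) {
        if (!is.list(e) || !all(c("role", "x", "y", "halfWidth") %in% names(e)))
            msg <- c(msg, "each electrode needs role, x, y, halfWidth")
        else {
            if (!e$role %in% c("phase", "neutral"))
                msg <- c(msg, "electrode role must be 'phase' or 'neutral'")
            if (any(e$x < 0) || any(e$x > object@length) ||
                any(e$y < 0) || any(e$y > object@width))
                msg <- c(msg, "electrode polyline outside channel bounds")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn DeviceGeometry-class Constructor.
#' @param length,width channel dimensions (m)
#' @param electrodes list of electrode segment descriptions
#' @param inletBand entry band (fractions of width)
#' @param split outlet split coordinate (m); default half-width
#' @return A \code{DeviceGeometry}.
#' @export
DeviceGeometry <- function(length, width, electrodes,
                           inletBand = c(0.70, 0.95), split = width / 2) {
    new("DeviceGeometry", length = length, width = width,
        electrodes = electrodes, inletBand = inletBand, split = split)
}

setMethod("show", "DeviceGeometry", function(object) {
    roles <- vapply(object@electrodes, `[[`, character(1), "role")
    cat(sprintf("DeviceGeometry: %.3g mm x %.3g um channel, %d electrodes (%s)\n",
        object@length * 1e3, object@width * 1e6, length(object@electrodes),
        paste(roles, collapse = ", ")))
})

#' Default diagonal-electrode sorter geometry
#'
#' A 5 mm x 500 um channel with a continuous oblique neutral electrode
#' running diagonally from the right wall (upstream) to the left wall
#' (downstream) and a phase electrode on its downstream-left side.  The
#' field-intensity maximum follows the diagonal gap between the two, so
#' cells that feel a DEP force are carried to the left side of the channel
#' while force-free cells (at their crossover frequency) pass straight
#' through and exit right.
#'
#' Two phase-electrode styles are available.  \code{"parallel"} (the
#' default) is a second continuous oblique strip at a fixed gap: in a plan
#' view the gap field is then translation-invariant along the diagonal, so
#' captured cells glide along it unimpeded.  \code{"fingers"} is a
#' finger-array phase electrode whose tips track the diagonal; it
#' reproduces the interdigitated layout of practical devices but in a
#' strict 2D plan view the discrete finger tips are local field maxima that
#' can pin captured cells in place (an artifact the real, finite-height
#' channel mitigates), so it is not the default.
#'
#' @param length,width channel dimensions (m)
#' @param stripHalfWidth electrode strip half-width (m); strips are 50 um wide
#' @param gap edge-to-edge clearance between phase and neutral
#'   electrodes (m)
#' @param style "parallel" or "fingers"
#' @param nFingers number of fingers for \code{style = "fingers"}
#' @return A \code{\linkS4class{DeviceGeometry}}.
#' @examples
#' defaultDeviceGeometry()
#' @export
defaultDeviceGeometry <- function(length = 5e-3, width = 5e-4,
                                  stripHalfWidth = 25e-6, gap = 150e-6,
                                  style = c("parallel", "fingers"),
                                  nFingers = 12L) {
    style <- match.arg(style)
    x0 <- 0.1 * length; x1 <- 0.9 * length
    diagY <- function(x) width * (x1 - x) / (x1 - x0)
    electrodes <- list(list(role = "neutral",
        x = c(x0, x1), y = c(width, 0), halfWidth = stripHalfWidth))
    if (style == "parallel") {
        ## centerline parallel to the neutral strip, offset so the
        ## edge-to-edge clearance equals `gap`
        cosA <- (x1 - x0) / sqrt((x1 - x0)^2 + width^2)
        dY <- (gap + 2 * stripHalfWidth) / cosA
        yA <- width - dY                      # phase line at x0
        xEnd <- x0 + (x1 - x0) * yA / width   # where it reaches y = 0
        electrodes[[2L]] <- list(role = "phase",
            x = c(x0, xEnd), y = c(yA, 0), halfWidth = stripHalfWidth)
    } else {
        xs <- seq(x0 + 0.05 * (x1 - x0), x1 - 0.02 * (x1 - x0),
                  length.out = nFingers)
        for (xf in xs) {
            yTip <- max(diagY(xf) - gap, 0)
            electrodes[[length(electrodes) + 1L]] <- list(role = "phase",
                x = c(xf, xf), y = c(0, yTip), halfWidth = stripHalfWidth)
        }
    }
    DeviceGeometry(length = length, width = width, electrodes = electrodes)
}

## distance from grid nodes (xg, yg outer product) to a polyline segment set
.maskElectrode <- function(xg, yg, e) {
    nx <- length(xg); ny <- length(yg)
    X <- matrix(xg, nx, ny); Y <- matrix(yg, nx, ny, byrow = TRUE)
    hit <- matrix(FALSE, nx, ny)
    for (s in seq_len(length(e$x) - 1L)) {
        ax <- e$x[s]; ay <- e$y[s]; bx <- e$x[s + 1L]; by <- e$y[s + 1L]
        dx <- bx - ax; dy <- by - ay
        L2 <- dx * dx + dy * dy
        t <- if (L2 > 0) pmin(pmax(((X - ax) * dx + (Y - ay) * dy) / L2, 0), 1)
             else 0
        d2 <- (X - (ax + t * dx))^2 + (Y - (ay + t * dy))^2
        hit <- hit | d2 <= e$halfWidth^2
    }
    hit
}

#' Solve the electrode potential in the channel
#'
#' Quasi-static (electric-currents) approximation: the RMS potential obeys
#' Laplace's equation on the channel interior with Dirichlet values
#' \code{vRms} on phase electrodes and 0 on neutral electrodes, and zero
#' normal flux on walls and openings.  Five-point finite differences with
#' mirrored ghost nodes at Neumann boundaries; the sparse system is solved
#' directly.
#'
#' @param geom a \code{\linkS4class{DeviceGeometry}}
#' @param nx,ny grid nodes along and across the channel (\code{ny >= 50})
#' @param vRms phase-electrode RMS voltage (V); default 10 V
#' @return A \code{\linkS4class{ScalarField2D}} of the RMS potential.
#' @export
solvePotential <- function(geom, nx = 501L, ny = 61L, vRms = 10) {
    validObject(geom)
    if (ny < 50L) stop("need at least 50 nodes across the channel width")
    if (!length(geom@electrodes)) stop("geometry has no electrodes")
    xg <- seq(0, geom@length, length.out = nx)
    yg <- seq(0, geom@width, length.out = ny)
    dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
    dirich <- matrix(NA_real_, nx, ny)
    for (e in geom@electrodes) {
        hit <- .maskElectrode(xg, yg, e)
        dirich[hit] <- if (e$role == "phase") vRms else 0
    }
    if (!any(!is.na(dirich))) stop("electrode rasterization hit no grid nodes")
    idx <- matrix(seq_len(nx * ny), nx, ny)
    ## assemble vectorized: for each node, neighbor contributions with
    ## mirror ghosts at boundaries.  Build via neighbor index arrays.
    I <- matrix(seq_len(nx), nx, ny); J <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    free <- is.na(dirich)
    ## neighbor linear indices with reflection at the boundary
    ip <- idx[cbind(pmin(as.vector(I) + 1L, nx), as.vector(J))]
    im <- idx[cbind(pmax(as.vector(I) - 1L, 1L), as.vector(J))]
    jp <- idx[cbind(as.vector(I), pmin(as.vector(J) + 1L, ny))]
    jm <- idx[cbind(as.vector(I), pmax(as.vector(J) - 1L, 1L))]
    ## reflection: at i = nx the +x neighbor mirrors to i-1, etc.
    ip[as.vector(I) == nx] <- idx[cbind(rep(nx - 1L, sum(I == nx)),
                                        as.vector(J)[as.vector(I) == nx])]
    im[as.vector(I) == 1L] <- idx[cbind(rep(2L, sum(I == 1L)),
                                        as.vector(J)[as.vector(I) == 1L])]
    jp[as.vector(J) == ny] <- idx[cbind(as.vector(I)[as.vector(J) == ny],
                                        rep(ny - 1L, sum(J == ny)))]
    jm[as.vector(J) == 1L] <- idx[cbind(as.vector(I)[as.vector(J) == 1L],
                                        rep(2L, sum(J == 1L)))]
    node <- as.vector(idx)
    isFree <- as.vector(free)
    cx <- 1 / dx^2; cy <- 1 / dy^2
    ## diagonal
    rows <- node[isFree]; cols <- node[isFree]
    vals <- rep(-2 * (cx + cy), sum(isFree))
    dirVec <- as.vector(dirich)
    rhs <- numeric(nx * ny)
    for (nb in list(list(n = ip, c = cx), list(n = im, c = cx),
                    list(n = jp, c = cy), list(n = jm, c = cy))) {
        nbi <- nb$n[isFree]
        tgtFree <- isFree[nbi]
        ## neighbor itself free: matrix entry; neighbor Dirichlet: to RHS
        rows <- c(rows, node[isFree][tgtFree])
        cols <- c(cols, nbi[tgtFree])
        vals <- c(vals, rep(nb$c, sum(tgtFree)))
        rhs[node[isFree][!tgtFree]] <- rhs[node[isFree][!tgtFree]] -
            nb$c * dirVec[nbi[!tgtFree]]
    }
    ## Dirichlet nodes: identity rows
    rows <- c(rows, node[!isFree]); cols <- c(cols, node[!isFree])
    vals <- c(vals, rep(1, sum(!isFree)))
    rhs[node[!isFree]] <- dirVec[!isFree]
    A <- sparseMatrix(i = rows, j = cols, x = vals, dims = c(nx * ny, nx * ny))
    V <- as.numeric(Matrix::solve(A, rhs))
    resid <- max(abs(A %*% V - rhs))
    bscale <- max(abs(rhs), 1e-12)
    if (resid > 1e-8 * bscale)
        stop(sprintf("potential solve did not converge: residual %.3g", resid))
    new("ScalarField2D", x = xg, y = yg, values = matrix(V, nx, ny))
}

## central differences (one-sided at boundaries) of a nodal matrix
.ddx <- function(M, x) {
    n <- nrow(M)
    out <- M
    out[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) /
        rep(x[3:n] - x[1:(n - 2)], ncol(M))
    out[1, ] <- (M[2, ] - M[1, ]) / (x[2] - x[1])
    out[n, ] <- (M[n, ] - M[n - 1, ]) / (x[n] - x[n - 1])
    out
}

.ddy <- function(M, y) t(.ddx(t(M), y))

#' Squared field intensity |E|^2 from a potential field
#'
#' @param V a \code{\linkS4class{ScalarField2D}} potential
#' @return A \code{\linkS4class{ScalarField2D}} of \eqn{|E|^2} (V^2/m^2).
#' @export
fieldIntensity <- function(V) {
    Ex <- -.ddx(V@values, V@x)
    Ey <- -.ddy(V@values, V@y)
    new("ScalarField2D", x = V@x, y = V@y, values = Ex^2 + Ey^2)
}

## separable moving-average with edge replication; w = half-width in nodes
.boxSmooth <- function(M, w) {
    if (w < 1L) return(M)
    sm1 <- function(A) {
        n <- nrow(A)
        pad <- rbind(A[rep(1L, w), , drop = FALSE], A,
                     A[rep(n, w), , drop = FALSE])
        cs <- apply(pad, 2L, cumsum)
        (cs[(2 * w + 1):(n + 2 * w), , drop = FALSE] -
         rbind(0, cs[seq_len(n - 1), , drop = FALSE])) / (2 * w + 1)
    }
    t(sm1(t(sm1(M))))
}

#' Gradient of the squared field intensity
#'
#' \eqn{\nabla |E|^2}, the drive of the DEP force, from central differences
#' of the solved potential (one-sided at boundaries).  Before
#' differentiation \eqn{|E|^2} is averaged over a square window of
#' half-width \code{smooth} (in metres): a cell samples the field over its
#' own finite volume, so the point singularities that ultra-thin electrode
#' edges produce in a plan-view solve are not felt at the particle scale.
#' Set \code{smooth = 0} for the raw nodal gradient.
#'
#' @param V a \code{\linkS4class{ScalarField2D}} potential
#' @param smooth finite-particle-size averaging half-width (m); default
#'   9 um, a typical cell radius
#' @return A \code{\linkS4class{VectorField2D}} of \eqn{\nabla|E|^2}
#'   (V^2/m^3).
#' @export
gradE2Field <- function(V, smooth = 9e-6) {
    e2 <- fieldIntensity(V)@values
    if (smooth > 0) {
        h <- min(V@x[2] - V@x[1], V@y[2] - V@y[1])
        e2 <- .boxSmooth(e2, as.integer(round(smooth / h)))
    }
    new("VectorField2D", x = V@x, y = V@y,
        vx = .ddx(e2, V@x), vy = .ddy(e2, V@y))
}

#' Fully developed laminar flow in the channel
#'
#' Plane-Poiseuille profile across the width:
#' \eqn{u(y) = 1.5\,\bar{u}\,[1 - (2(y - w/2)/w)^2]}, zero lateral
#' component, no-slip at the walls.
#'
#' @param geom a \code{\linkS4class{DeviceGeometry}}
#' @param meanSpeed cross-section average speed (m/s, > 0)
#' @param nx,ny grid resolution
#' @return A \code{\linkS4class{VectorField2D}} of the fluid velocity.
#' @export
flowField <- function(geom, meanSpeed, nx = 501L, ny = 61L) {
    if (!(meanSpeed > 0)) stop("meanSpeed must be positive")
    xg <- seq(0, geom@length, length.out = nx)
    yg <- seq(0, geom@width, length.out = ny)
    prof <- 1.5 * meanSpeed * (1 - (2 * (yg - geom@width / 2) / geom@width)^2)
    new("VectorField2D", x = xg, y = yg,
        vx = matrix(prof, nx, ny, byrow = TRUE),
        vy = matrix(0, nx, ny))
}

## bilinear interpolation of a nodal matrix at arbitrary points (vectorized)
.bilinear <- function(xg, yg, M, px, py) {
    nx <- length(xg); ny <- length(yg)
    dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
    fx <- (px - xg[1]) / dx
    fy <- (py - yg[1]) / dy
    i <- pmin(pmax(floor(fx), 0), nx - 2L); tx <- fx - i
    j <- pmin(pmax(floor(fy), 0), ny - 2L); ty <- fy - j
    tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
    i <- as.integer(i) + 1L; j <- as.integer(j) + 1L
    M[cbind(i, j)] * (1 - tx) * (1 - ty) +
        M[cbind(i + 1L, j)] * tx * (1 - ty) +
        M[cbind(i, j + 1L)] * (1 - tx) * ty +
        M[cbind(i + 1L, j + 1L)] * tx * ty
}
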