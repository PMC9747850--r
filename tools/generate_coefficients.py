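#!/usr/bin/env python
"""One-off generator for the bundled per-element photon coefficient tables.

Writes inst/extdata/coefficients/<symbol>.csv with columns
energy_mev, mu_rho, mu_en_rho (cm^2/g).

Physics model (matches the transport engine's interaction model exactly):
  * incoherent scattering: free-electron Klein-Nishina, closed form;
  * photoabsorption: Cromer-Liberman cross-sections (gemmi), photon fully
    absorbed locally (no fluorescence), so it contributes equally to
    attenuation and energy absorption;
  * coherent (Rayleigh) scattering excluded -- it moves no energy and the
    transport engine does not model it;
  * mu_en counts the Klein-Nishina energy-transfer cross-section plus the
    full photoabsorption term (kerma-approximation bookkeeping: radiative
    losses are negligible below 1.4 MeV).

Run from the repository root:  python tools/generate_coefficients.py
"""
import math
import os

import gemmi

NA = 6.02214076e23
RE = 2.8179403262e-13   # classical electron radius, cm
MEC2 = 0.51099895       # electron rest energy, MeV

# symbol: (Z, atomic mass, K-edge keV if inside [10, 1400] keV else None)
ELEMENTS = {
    "H": (1, 1.008, None),   "C": (6, 12.011, None),  "N": (7, 14.007, None),
    "O": (8, 15.999, None),  "Na": (11, 22.990, None), "Mg": (12, 24.305, None),
    "Al": (13, 26.982, None), "Si": (14, 28.085, None), "P": (15, 30.974, None),
    "S": (16, 32.06, None),  "Cl": (17, 35.45, None), "Ar": (18, 39.948, None),
    "K": (19, 39.098, None), "Ca": (20, 40.078, None), "Ti": (22, 47.867, None),
    "V": (23, 50.942, None), "Cr": (24, 51.996, None), "Mn": (25, 54.938, None),
    "Fe": (26, 55.845, None), "Ni": (28, 58.693, None), "Zn": (30, 65.38, None),
    "Mo": (42, 95.95, 19.9995), "Ir": (77, 192.217, 76.112),
}

EMIN, EMAX, NGRID = 0.010, 1.400, 100


def kn_total(e_mev):
    """Klein-Nishina total cross-section per electron, cm^2."""
    a = e_mev / MEC2
    t = 1.0 + 2.0 * a
    return 2.0 * math.pi * RE * RE * (
        (1.0 + a) / (a * a) * (2.0 * (1.0 + a) / t - math.log(t) / a)
        + math.log(t) / (2.0 * a) - (1.0 + 3.0 * a) / (t * t))


def kn_scatter(e_mev):
    """KN energy-scattering cross-section (energy kept by the photon)."""
    a = e_mev / MEC2
    t = 1.0 + 2.0 * a
    return math.pi * RE * RE * (
        math.log(t) / a ** 3
        + 2.0 * (1.0 + a) * (2.0 * a * a - 2.0 * a - 1.0) / (a * a * t * t)
        + 8.0 * a * a / (3.0 * t ** 3))


def sigma_pe(z, e_mev):
    """Photoabsorption cross-section per atom, cm^2, from Cromer-Liberman f''."""
    e_ev = e_mev * 1.0e6
    _, fpp = gemmi.cromer_liberman(z=z, energy=e_ev)
    if fpp < 0.0:
        fpp = 0.0
    return 2.0 * RE * (1.23984198e-4 / e_ev) * fpp


def energy_grid(k_edge_kev):
    grid = [EMIN * (EMAX / EMIN) ** (i / (NGRID - 1)) for i in range(NGRID)]
    if k_edge_kev is not None:
        ek = k_edge_kev * 1e-3
        grid += [ek * (1 - 1e-4), ek * (1 + 1e-4)]
    return sorted(grid)


def main():
    out = os.path.join("inst", "extdata", "coefficients")
    os.makedirs(out, exist_ok=True)
    for sym, (z, a, edge) in ELEMENTS.items():
        rows = []
        for e in energy_grid(edge):
            pe = sigma_pe(z, e)
            mu = NA / a * (z * kn_total(e) + pe)
            muen = NA / a * (z * (kn_total(e) - kn_scatter(e)) + pe)
            rows.append((e, mu, muen))
        with open(os.path.join(out, sym + ".csv"), "w") as fh:
            fh.write("# element %s (Z=%d, A=%.3f)\n" % (sym, z, a))
            fh.write("# mass attenuation / mass energy-absorption coefficients,"
                     " cm^2/g\n")
            fh.write("# incoherent: free-electron Klein-Nishina;"
                     " photoabsorption: Cromer-Liberman (gemmi);"
                     " coherent excluded; no fluorescence\n")
            fh.write("energy_mev,mu_rho,mu_en_rho\n")
            for e, mu, muen in rows:
                fh.write("%.8e,%.8e,%.8e\n" % (e, mu, muen))
        print(sym, "ok")


if __name__ == "__main__":
    main()
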