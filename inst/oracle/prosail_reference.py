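"""Reference transcription of the coupled leaf/canopy radiative transfer model.

Scalar NumPy/SciPy implementation of the generalised plate leaf model and the
four-stream turbid-medium canopy model, written independently of the R code
so the two routes can be cross-checked. It is driven entirely by CSV files:

    python prosail_reference.py CONSTANTS.csv PARAMS.csv SOIL.csv OUT.csv

CONSTANTS.csv: wavelength,nr,kab,kcar,kbrown,kw,km (1 nm grid, 400-2500)
PARAMS.csv:    N,Cab,Ccx,Cbp,Cw,Cm,LAI,ALIA,hot,SZA,OZA,rAA (one row per case)
SOIL.csv:      wavelength,value (soil background reflectance)
OUT.csv:       set,wavelength,leaf_refl,leaf_tran,brf (long table)
"""

import csv
import math
import sys

import numpy as np
from scipy.special import exp1


def tav(theta_deg, ref):
    """Mean transmissivity of a dielectric interface for a cone of incidence."""
    if theta_deg == 0:
        return 4.0 * ref / (ref + 1.0) ** 2
    s2 = math.sin(math.radians(theta_deg)) ** 2
    r2 = ref * ref
    ax = (ref + 1.0) ** 2 / 2.0
    bx = -((r2 - 1.0) ** 2) / 4.0
    if theta_deg == 90:
        b1 = np.zeros_like(ref)
    else:
        b1 = np.sqrt((s2 - (r2 + 1.0) / 2.0) ** 2 + bx)
    b2 = s2 - (r2 + 1.0) / 2.0
    b0 = b1 - b2
    ts = (bx ** 2 / (6.0 * b0 ** 3) + bx / b0 - b0 / 2.0) - (
        bx ** 2 / (6.0 * ax ** 3) + bx / ax - ax / 2.0
    )
    tp1 = -2.0 * r2 * (b0 - ax) / (r2 + 1.0) ** 2
    tp2 = -2.0 * r2 * (r2 + 1.0) * np.log(b0 / ax) / (r2 - 1.0) ** 2
    tp3 = r2 * (1.0 / b0 - 1.0 / ax) / 2.0
    q1 = 2.0 * (r2 + 1.0) * b0 - (r2 - 1.0) ** 2
    q2 = 2.0 * (r2 + 1.0) * ax - (r2 - 1.0) ** 2
    tp4 = 16.0 * r2 ** 2 * (r2 ** 2 + 1.0) * np.log(q1 / q2) / (
        (r2 + 1.0) ** 3 * (r2 - 1.0) ** 2
    )
    tp5 = 16.0 * r2 ** 3 * (1.0 / q1 - 1.0 / q2) / (r2 + 1.0) ** 3
    return (ts + tp1 + tp2 + tp3 + tp4 + tp5) / (2.0 * s2)


def leaf_plate_model(const, n_struct, cab, ccx, cbp, cw, cm):
    k = (
        cab * const["kab"]
        + ccx * const["kcar"]
        + cbp * const["kbrown"]
        + cw * const["kw"]
        + cm * const["km"]
    ) / n_struct
    trans = np.ones_like(k)
    pos = k > 0
    trans[pos] = (1.0 - k[pos]) * np.exp(-k[pos]) + k[pos] ** 2 * exp1(k[pos])
    trans = np.clip(trans, 0.0, 1.0)

    nr = const["nr"]
    talf = tav(40.0, nr)
    ralf = 1.0 - talf
    t12 = tav(90.0, nr)
    r12 = 1.0 - t12
    t21 = t12 / nr ** 2
    r21 = 1.0 - t21

    denom = 1.0 - r21 ** 2 * trans ** 2
    ta = talf * trans * t21 / denom
    ra = ralf + r21 * ta * trans
    t = t12 * trans * t21 / denom
    r = r12 + r21 * t * trans

    disc = (1.0 + r + t) * (1.0 + r - t) * (1.0 - r + t) * (1.0 - r - t)
    d = np.sqrt(np.maximum(disc, 0.0))
    rq = r ** 2
    tq = t ** 2
    a = (1.0 + rq - tq + d) / (2.0 * r)
    b = (1.0 - rq + tq + d) / (2.0 * t)
    bnm1 = np.power(b, n_struct - 1.0)
    bn2 = bnm1 ** 2
    a2 = a ** 2
    denom2 = a2 * bn2 - 1.0
    rsub = a * (bn2 - 1.0) / denom2
    tsub = bnm1 * (a2 - 1.0) / denom2
    conservative = (r + t) >= 1.0
    tsub[conservative] = t[conservative] / (
        t[conservative] + (1.0 - t[conservative]) * (n_struct - 1.0)
    )
    rsub[conservative] = 1.0 - tsub[conservative]
    denom3 = 1.0 - rsub * r
    leaf_tran = ta * tsub / denom3
    leaf_refl = ra + ta * rsub * t / denom3
    return leaf_refl, leaf_tran


def campbell(alia):
    """Ellipsoidal leaf inclination distribution over 13 angle classes."""
    lo = list(range(0, 80, 10)) + list(range(80, 90, 2))
    hi = list(range(10, 90, 10)) + list(range(82, 92, 2))
    exc = math.exp(
        -1.6184e-5 * alia ** 3 + 2.1145e-3 * alia ** 2 - 1.2390e-1 * alia + 3.2491
    )
    freq = []
    for l, h in zip(lo, hi):
        tl1 = math.radians(l)
        tl2 = math.radians(h)
        x1 = exc / math.sqrt(1.0 + exc ** 2 * math.tan(tl1) ** 2)
        x2 = exc / math.sqrt(1.0 + exc ** 2 * math.tan(tl2) ** 2)
        if exc == 1.0:
            freq.append(abs(math.cos(tl1) - math.cos(tl2)))
            continue
        alph = exc / math.sqrt(abs(1.0 - exc ** 2))
        a2 = alph ** 2
        if exc > 1.0:
            ax1 = math.sqrt(a2 + x1 ** 2)
            ax2 = math.sqrt(a2 + x2 ** 2)
            dum = x1 * ax1 + a2 * math.log(x1 + ax1)
            freq.append(abs(dum - (x2 * ax2 + a2 * math.log(x2 + ax2))))
        else:
            am1 = math.sqrt(a2 - x1 ** 2)
            am2 = math.sqrt(a2 - x2 ** 2)
            dum = x1 * am1 + a2 * math.asin(x1 / alph)
            freq.append(abs(dum - (x2 * am2 + a2 * math.asin(x2 / alph))))
    total = sum(freq)
    mid = [(l + h) / 2.0 for l, h in zip(lo, hi)]
    return mid, [f / total for f in freq]


def volscatt(tts, tto, psi, ttl):
    costs = math.cos(math.radians(tts))
    costo = math.cos(math.radians(tto))
    sints = math.sin(math.radians(tts))
    sinto = math.sin(math.radians(tto))
    cospsi = math.cos(math.radians(psi))
    psir = math.radians(psi)
    costl = math.cos(math.radians(ttl))
    sintl = math.sin(math.radians(ttl))
    cs = costl * costs
    co = costl * costo
    ss = sintl * sints
    so = sintl * sinto

    cosbts = 5.0
    if abs(ss) > 1e-6:
        cosbts = -cs / ss
    cosbto = 5.0
    if abs(so) > 1e-6:
        cosbto = -co / so

    if abs(cosbts) < 1.0:
        bts = math.acos(cosbts)
        ds = ss
    else:
        bts = math.pi
        ds = cs
    chi_s = 2.0 / math.pi * ((bts - math.pi * 0.5) * cs + math.sin(bts) * ss)

    if abs(cosbto) < 1.0:
        bto = math.acos(cosbto)
        do_ = so
    elif tto < 90.0:
        bto = math.pi
        do_ = co
    else:
        bto = 0.0
        do_ = -co
    chi_o = 2.0 / math.pi * ((bto - math.pi * 0.5) * co + math.sin(bto) * so)

    btran1 = abs(bts - bto)
    btran2 = math.pi - abs(bts + bto - math.pi)
    if psir <= btran1:
        bt1, bt2, bt3 = psir, btran1, btran2
    elif psir <= btran2:
        bt1, bt2, bt3 = btran1, psir, btran2
    else:
        bt1, bt2, bt3 = btran1, btran2, psir

    t1 = 2.0 * cs * co + ss * so * cospsi
    t2 = 0.0
    if bt2 > 0.0:
        t2 = math.sin(bt2) * (2.0 * ds * do_ + ss * so * math.cos(bt1) * math.cos(bt3))
    denom = 2.0 * math.pi ** 2
    frho = max(((math.pi - bt2) * t1 + t2) / denom, 0.0)
    ftau = max((-bt1 * t1 + t2) / denom, 0.0)
    return chi_s, chi_o, frho, ftau


def jfunc1(k, l, t):
    del_ = (k - l) * t
    out = np.empty_like(l)
    near = np.abs(del_) < 1e-3
    out[~near] = (np.exp(-l[~near] * t) - np.exp(-k * t)) / (k - l[~near])
    out[near] = (
        0.5 * t * (np.exp(-k * t) + np.exp(-l[near] * t)) * (1.0 - del_[near] ** 2 / 12.0)
    )
    return out


def jfunc2(k, l, t):
    return (1.0 - np.exp(-(k + l) * t)) / (k + l)


def canopy_four_stream(rho, tau, lai, alia, hotspot, tts, tto, psi, rsoil):
    if lai <= 0.0:
        return rsoil.copy()
    cts = math.cos(math.radians(tts))
    cto = math.cos(math.radians(tto))
    ctscto = cts * cto
    tants = math.tan(math.radians(tts))
    tanto = math.tan(math.radians(tto))
    cospsi = math.cos(math.radians(psi))
    dso = math.sqrt(tants ** 2 + tanto ** 2 - 2.0 * tants * tanto * cospsi)

    angles, freqs = campbell(alia)
    ks = ko = bf = sob = sof = 0.0
    for ang, f in zip(angles, freqs):
        chi_s, chi_o, frho, ftau = volscatt(tts, tto, psi, ang)
        ks += chi_s / cts * f
        ko += chi_o / cto * f
        sob += frho * math.pi / ctscto * f
        sof += ftau * math.pi / ctscto * f
        bf += math.cos(math.radians(ang)) ** 2 * f

    sdb = 0.5 * (ks + bf)
    sdf = 0.5 * (ks - bf)
    dob = 0.5 * (ko + bf)
    dof = 0.5 * (ko - bf)
    ddb = 0.5 * (1.0 + bf)
    ddf = 0.5 * (1.0 - bf)

    sigb = ddb * rho + ddf * tau
    sigf = ddf * rho + ddb * tau
    att = 1.0 - sigf
    m = np.sqrt(np.maximum((att + sigb) * (att - sigb), 0.0))
    sb = sdb * rho + sdf * tau
    sf = sdf * rho + sdb * tau
    vb = dob * rho + dof * tau
    vf = dof * rho + dob * tau
    w = sob * rho + sof * tau

    e1 = np.exp(-m * lai)
    e2 = e1 ** 2
    sigb = np.where(sigb == 0.0, 1e-36, sigb)
    rinf = (att - m) / sigb
    rinf2 = rinf ** 2
    re = rinf * e1
    denom = 1.0 - rinf2 * e2

    j1ks = jfunc1(ks, m, lai)
    j2ks = jfunc2(ks, m, lai)
    j1ko = jfunc1(ko, m, lai)
    j2ko = jfunc2(ko, m, lai)

    ps = (sf + sb * rinf) * j1ks
    qs = (sf * rinf + sb) * j2ks
    pv = (vf + vb * rinf) * j1ko
    qv = (vf * rinf + vb) * j2ko

    rdd = rinf * (1.0 - e2) / denom
    tdd = (1.0 - rinf2) * e1 / denom
    tsd = (ps - re * qs) / denom
    rsd = (qs - re * ps) / denom
    tdo = (pv - re * qv) / denom
    rdo = (qv - re * pv) / denom

    tss = math.exp(-ks * lai)
    too = math.exp(-ko * lai)
    z = jfunc2(ks, ko, lai)
    g1 = (z - j1ks * too) / (ko + m)
    g2 = (z - j1ko * tss) / (ks + m)
    tv1 = (vf * rinf + vb) * g1
    tv2 = (vf + vb * rinf) * g2
    t1 = tv1 * (sf + sb * rinf)
    t2 = tv2 * (sf * rinf + sb)
    t3 = (rdo * qs + tdo * ps) * rinf
    rsod = (t1 + t2 - t3) / (1.0 - rinf2)

    alf = 1e36
    if hotspot > 0.0:
        alf = (dso / hotspot) * 2.0 / (ks + ko)
    if alf == 0.0:
        tsstoo = tss
        sumint = (1.0 - tss) / (ks * lai)
    else:
        fhot = lai * math.sqrt(ko * ks)
        x1 = 0.0
        y1 = 0.0
        f1 = 1.0
        fint = (1.0 - math.exp(-alf)) * 0.05
        sumint = 0.0
        for i in range(1, 21):
            x2 = 1.0 if i == 20 else -math.log(1.0 - i * fint) / alf
            y2 = -(ko + ks) * lai * x2 + fhot * (1.0 - math.exp(-alf * x2)) / alf
            f2 = math.exp(y2)
            sumint += (f2 - f1) * (x2 - x1) / (y2 - y1)
            x1, y1, f1 = x2, y2, f2
        tsstoo = f1
        if math.isnan(sumint):
            sumint = 0.0

    rsos = w * lai * sumint
    rso = rsos + rsod
    dn = 1.0 - rsoil * rdd
    rsodt = ((tss + tsd) * tdo + (tsd + tss * rsoil * rdd) * too) * rsoil / dn
    rsost = rso + tsstoo * rsoil
    return rsost + rsodt


def read_columns(path):
    with open(path, newline="") as fh:
        rows = list(csv.DictReader(fh))
    return {k: np.array([float(r[k]) for r in rows]) for k in rows[0]}


def main(argv):
    const_path, params_path, soil_path, out_path = argv[1:5]
    const = read_columns(const_path)
    soil = read_columns(soil_path)["value"]
    with open(params_path, newline="") as fh:
        params = list(csv.DictReader(fh))
    wl = const["wavelength"].astype(int)
    with open(out_path, "w", newline="") as fh:
        out = csv.writer(fh)
        out.writerow(["set", "wavelength", "leaf_refl", "leaf_tran", "brf"])
        for i, p in enumerate(params):
            p = {k: float(v) for k, v in p.items()}
            lr, lt = leaf_plate_model(
                const, p["N"], p["Cab"], p["Ccx"], p["Cbp"], p["Cw"], p["Cm"]
            )
            brf = canopy_four_stream(
                lr, lt, p["LAI"], p["ALIA"], p["hot"], p["SZA"], p["OZA"], p["rAA"], soil
            )
            for j in range(len(wl)):
                out.writerow(
                    [i + 1, wl[j], repr(float(lr[j])), repr(float(lt[j])),
                     repr(float(brf[j]))]
                )
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
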