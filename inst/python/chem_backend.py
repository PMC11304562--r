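"""Batch chemistry backend for the rulepath R package.

Reads a JSON request from argv[1], writes a JSON response to argv[2].
All structure identity is stereo-stripped canonical SMILES.  The request
may contain any of the keys below; each is processed independently so a
single subprocess invocation can serve a whole batch of work.

request = {
  "canon":  [smiles, ...],
  "fp":     [smiles, ...],                       # Morgan radius-2 bits
  "fp_nbits": 2048,                              # optional
  "apply":  [{"smirks": s, "smiles": [..]}, ...],
  "smarts": {"patterns": {id: smarts}, "smiles": [..]}
}

response = {
  "canon":  [{"in": s, "out": canon} | {"in": s, "error": msg}, ...],
  "fp":     {smiles: [bit, ...]},
  "apply":  [{"smirks": s,
              "results": {smiles: [[prod, ...], ...]},   # product sets
              "dropped": {smiles: n}},                   # sanitize fails
             ...],
  "smarts": {smiles: {id: [[atom, ...], ...]}}
}
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def strip_mol(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    Chem.RemoveStereochemistry(mol)
    return mol


def canonical(smiles):
    mol = strip_mol(smiles)
    return None if mol is None else Chem.MolToSmiles(mol)


def do_canon(smiles_list):
    out = []
    for smi in smiles_list:
        can = canonical(smi)
        if can is None:
            out.append({"in": smi, "error": "unparseable SMILES"})
        else:
            out.append({"in": smi, "out": can})
    return out


def do_fp(smiles_list, nbits):
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=nbits)
    out = {}
    for smi in smiles_list:
        mol = strip_mol(smi)
        if mol is None:
            out[smi] = None
            continue
        fp = gen.GetFingerprint(mol)
        out[smi] = sorted(fp.GetOnBits())
    return out


def apply_one(rxn, mol):
    """One product set per distinct match site, sanitized, canonical, deduped."""
    seen = set()
    sets = []
    dropped = 0
    for prods in rxn.RunReactants((mol,)):
        cur = []
        ok = True
        for p in prods:
            try:
                Chem.SanitizeMol(p)
            except Exception:
                ok = False
                break
            can = canonical(Chem.MolToSmiles(p))
            if can is None:
                ok = False
                break
            cur.append(can)
        if not ok:
            dropped += 1
            continue
        key = tuple(sorted(cur))
        if key not in seen:
            seen.add(key)
            sets.append(sorted(cur))
    sets.sort()
    return sets, dropped


def do_apply(jobs):
    out = []
    for job in jobs:
        smirks = job["smirks"]
        try:
            rxn = AllChem.ReactionFromSmarts(smirks)
            if rxn is None:
                raise ValueError("null reaction")
            rxn.Initialize()
        except Exception as exc:  # malformed SMIRKS
            out.append({"smirks": smirks, "error": "unparseable SMIRKS: %s" % exc})
            continue
        results = {}
        dropped = {}
        for smi in job["smiles"]:
            mol = strip_mol(smi)
            if mol is None:
                results[smi] = None
                continue
            sets, ndrop = apply_one(rxn, mol)
            results[smi] = sets
            if ndrop:
                dropped[smi] = ndrop
        out.append({"smirks": smirks, "results": results, "dropped": dropped})
    return out


def do_smarts(spec):
    pats = {}
    for pid, smarts in spec["patterns"].items():
        q = Chem.MolFromSmarts(smarts)
        if q is None:
            raise ValueError("unparseable SMARTS for %s: %s" % (pid, smarts))
        pats[pid] = q
    out = {}
    for smi in spec["smiles"]:
        mol = strip_mol(smi)
        if mol is None:
            out[smi] = None
            continue
        hits = {}
        for pid, q in pats.items():
            matches = mol.GetSubstructMatches(q, uniquify=True)
            if matches:
                hits[pid] = [list(m) for m in matches]
        out[smi] = hits
    return out


def handle(req):
    resp = {}
    if req.get("canon"):
        resp["canon"] = do_canon(req["canon"])
    if req.get("fp"):
        resp["fp"] = do_fp(req["fp"], int(req.get("fp_nbits", 2048)))
    if req.get("apply"):
        resp["apply"] = do_apply(req["apply"])
    if req.get("smarts"):
        resp["smarts"] = do_smarts(req["smarts"])
    return resp


def serve(port):
    """Line-oriented request/response server on localhost for callers that
    want to amortize interpreter startup; exits when the client hangs up."""
    import socket

    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.setsockopt(socket.SOL_SOCKET, socket.SO_REUSEADDR, 1)
    srv.bind(("127.0.0.1", port))
    srv.listen(1)
    srv.settimeout(60)  # exit rather than linger if the client never comes
    try:
        conn, _ = srv.accept()
    except socket.timeout:
        srv.close()
        return
    conn.settimeout(None)
    fh = conn.makefile("rw", encoding="utf-8")
    for line in fh:
        line = line.strip()
        if not line:
            continue
        try:
            resp = handle(json.loads(line))
        except Exception as exc:
            resp = {"fatal": str(exc)}
        fh.write(json.dumps(resp) + "\n")
        fh.flush()
    conn.close()
    srv.close()


def main(argv):
    if argv[1] == "--serve":
        serve(int(argv[2]))
        return
    with open(argv[1]) as fh:
        req = json.load(fh)
    resp = handle(req)
    with open(argv[2], "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main(sys.argv)
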