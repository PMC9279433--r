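#!/usr/bin/env python
"""Batched RDKit services for the phenoflux R package.

Reads one JSON document on stdin: {"requests": [...]}, writes one JSON
document on stdout: {"results": [...]} with one entry per request, in
order.  Request kinds:

  {"op": "standardize", "records": [{"id", "smiles"?, "inchi"?, "molblock"?}]}
  {"op": "apply", "tasks": [{"rule_id", "smarts", "substrate"}]}
  {"op": "tanimoto", "pairs": [{"a", "b"}]}
  {"op": "match", "tasks": [{"smarts", "structure"}]}

Structures are SMILES unless they start with "InChI=".  Every emitted
structure is standardized to canonical InChI / canonical SMILES with an
explicit element->count formula (hydrogens included) and formal charge.
"""

import json
import sys
from collections import Counter

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, DataStructs
from rdkit.Chem.rdFingerprintGenerator import GetMorganGenerator

RDLogger.DisableLog("rdApp.*")

_FPGEN = GetMorganGenerator(radius=2, fpSize=2048)


def _parse(structure, molblock=None):
    if molblock:
        return Chem.MolFromMolBlock(molblock)
    if structure is None:
        return None
    s = structure.strip()
    if s.startswith("InChI="):
        return Chem.MolFromInchi(s)
    return Chem.MolFromSmiles(s)


def _formula(mol):
    mh = Chem.AddHs(mol)
    counts = Counter(a.GetSymbol() for a in mh.GetAtoms())
    return dict(sorted(counts.items()))


def _describe(mol):
    inchi = Chem.MolToInchi(mol)
    if not inchi:
        raise ValueError("InChI generation failed")
    return {
        "inchi": inchi,
        "smiles": Chem.MolToSmiles(mol),
        "formula": _formula(mol),
        "charge": Chem.GetFormalCharge(mol),
    }


def op_standardize(req):
    out = []
    for rec in req["records"]:
        rid = rec.get("id")
        try:
            mol = _parse(rec.get("smiles") or rec.get("inchi"),
                         rec.get("molblock"))
            if mol is None:
                raise ValueError("unparseable structure")
            d = _describe(mol)
            d["id"] = rid
            out.append(d)
        except Exception as exc:  # report per-record, never abort the batch
            out.append({"id": rid, "error": str(exc)})
    return out


def op_apply(req):
    out = []
    for task in req["tasks"]:
        try:
            rxn = AllChem.ReactionFromSmarts(task["smarts"])
            if rxn is None:
                raise ValueError("SMARTS compilation failed")
            sub = _parse(task["substrate"])
            if sub is None:
                raise ValueError("unparseable substrate")
            product_sets = []
            seen = set()
            for prods in rxn.RunReactants((sub,)):
                described = []
                ok = True
                for p in prods:
                    try:
                        Chem.SanitizeMol(p)
                        described.append(_describe(p))
                    except Exception:
                        ok = False
                        break
                if not ok or not described:
                    continue
                key = tuple(sorted(d["inchi"] for d in described))
                if key in seen:
                    continue
                seen.add(key)
                product_sets.append(described)
            out.append({"rule_id": task.get("rule_id"),
                        "product_sets": product_sets})
        except Exception as exc:
            out.append({"rule_id": task.get("rule_id"), "error": str(exc)})
    return out


def op_tanimoto(req):
    out = []
    cache = {}

    def fp(s):
        if s not in cache:
            mol = _parse(s)
            if mol is None:
                raise ValueError("unparseable structure: %s" % s)
            cache[s] = _FPGEN.GetFingerprint(mol)
        return cache[s]

    for pair in req["pairs"]:
        try:
            out.append(DataStructs.TanimotoSimilarity(fp(pair["a"]),
                                                      fp(pair["b"])))
        except Exception as exc:
            out.append({"error": str(exc)})
    return out


def op_match(req):
    out = []
    for task in req["tasks"]:
        try:
            patt = Chem.MolFromSmarts(task["smarts"])
            mol = _parse(task["structure"])
            if patt is None or mol is None:
                raise ValueError("unparseable pattern or structure")
            out.append(bool(mol.HasSubstructMatch(patt)))
        except Exception as exc:
            out.append({"error": str(exc)})
    return out


OPS = {
    "standardize": op_standardize,
    "apply": op_apply,
    "tanimoto": op_tanimoto,
    "match": op_match,
}


def main():
    payload = json.load(sys.stdin)
    results = []
    for req in payload["requests"]:
        handler = OPS.get(req.get("op"))
        if handler is None:
            results.append({"error": "unknown op: %r" % req.get("op")})
        else:
            results.append(handler(req))
    json.dump({"results": results}, sys.stdout)


if __name__ == "__main__":
    main()
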