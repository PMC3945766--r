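"""Batched RDKit chemistry primitives for the mmpairs R package.

Reads one JSON request {"op": ..., "payload": {...}} on stdin, writes one JSON
response {"ok": true, "result": {...}} (or {"ok": false, "error": msg}) on
stdout.  All operations are vectorized over records so the R side pays the
interpreter start-up cost once per batch, never per molecule.

Conventions:
  * attachment points are a single unlabelled dummy atom "*"
  * the hydrogen pseudo-fragment is the literal string "[*][H]" (0 heavy atoms)
  * atom indices refer to RDKit's parse order of the SMILES string passed in,
    so bond indices line up between the `cuts` and `retro_bonds` operations as
    long as both receive the same canonical SMILES.
"""

import json
import sys

from rdkit import Chem, RDLogger

RDLogger.DisableLog("rdApp.*")

H_FRAGMENT = "[*][H]"

# Standard neutralization pattern: protonatable cations (+1 with >=1 H) and
# deprotonated anions (-1), excluding charge-separated groups such as nitro
# or N-oxides whose charges cancel internally and cannot be "rebalanced" by
# adding/removing a proton.
NEUTRALIZE_PATTERN = Chem.MolFromSmarts(
    "[+1!h0!$([*]~[-1,-2,-3,-4]),-1!$([*]~[+1,+2,+3,+4])]"
)


def heavy_count(mol):
    return sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() > 1)


def neutralize(mol):
    for (idx,) in mol.GetSubstructMatches(NEUTRALIZE_PATTERN):
        atom = mol.GetAtomWithIdx(idx)
        chg = atom.GetFormalCharge()
        hcount = atom.GetTotalNumHs()
        if chg > 0 and hcount < chg:
            continue  # nothing to deprotonate without breaking valence
        atom.SetFormalCharge(0)
        atom.SetNumExplicitHs(hcount - chg)
        atom.UpdatePropertyCache()
    Chem.SanitizeMol(mol)
    return mol


def largest_component(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    if len(frags) == 1:
        return frags[0]
    organic = [f for f in frags
               if any(a.GetAtomicNum() == 6 for a in f.GetAtoms())]
    pool = organic if organic else list(frags)
    # largest heavy-atom count; ties broken by lexicographically smallest
    # canonical SMILES so component selection is deterministic
    keyed = sorted(pool, key=lambda f: (-heavy_count(f), Chem.MolToSmiles(f)))
    return keyed[0]


def op_standardize(payload):
    out = {"id": [], "input_smiles": [], "canonical_smiles": [],
           "heavy_atoms": [], "error": []}
    for rec in payload["records"]:
        smi = rec["smiles"]
        out["id"].append(rec["id"])
        out["input_smiles"].append(smi)
        try:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                raise ValueError("unparsable SMILES")
            mol = largest_component(mol)
            mol = neutralize(mol)
            can = Chem.MolToSmiles(mol)
            if can == "":
                raise ValueError("empty structure after standardization")
            out["canonical_smiles"].append(can)
            out["heavy_atoms"].append(heavy_count(mol))
            out["error"].append("")
        except Exception as exc:  # record-level failure, never batch abort
            out["canonical_smiles"].append(None)
            out["heavy_atoms"].append(None)
            out["error"].append(str(exc))
    return out


def op_heavy_atoms(payload):
    out = {"smiles": [], "heavy_atoms": [], "error": []}
    for smi in payload["fragments"]:
        out["smiles"].append(smi)
        if smi == H_FRAGMENT:
            out["heavy_atoms"].append(0)
            out["error"].append("")
            continue
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out["heavy_atoms"].append(None)
            out["error"].append("unparsable SMILES")
            continue
        ndummy = sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() == 0)
        if ndummy > 1:
            out["heavy_atoms"].append(None)
            out["error"].append("more than one attachment atom")
            continue
        out["heavy_atoms"].append(heavy_count(mol))
        out["error"].append("")
    return out


def cleavable_bonds(mol):
    """Acyclic single bonds between two heavy atoms."""
    for b in mol.GetBonds():
        if (b.GetBondType() == Chem.BondType.SINGLE
                and not b.IsInRing()
                and b.GetBeginAtom().GetAtomicNum() > 1
                and b.GetEndAtom().GetAtomicNum() > 1):
            yield b


def split_on_bond(mol, bond):
    """Return ((smiles, heavy) for begin side, (smiles, heavy) for end side)."""
    em = Chem.FragmentOnBonds(mol, [bond.GetIdx()], addDummies=True,
                              dummyLabels=[(0, 0)])
    idx_groups = Chem.GetMolFrags(em)
    frags = Chem.GetMolFrags(em, asMols=True, sanitizeFrags=True)
    begin = bond.GetBeginAtomIdx()
    if begin in idx_groups[0]:
        side_b, side_e = frags[0], frags[1]
    else:
        side_b, side_e = frags[1], frags[0]
    return ((Chem.MolToSmiles(side_b), heavy_count(side_b)),
            (Chem.MolToSmiles(side_e), heavy_count(side_e)))


def op_cuts(payload):
    hydrogen = payload.get("hydrogen", True)
    out = {"id": [], "core": [], "fragment": [], "core_heavy": [],
           "frag_heavy": [], "a1": [], "a2": [], "kind": []}

    def emit(cid, core, frag, ch, fh, a1, a2, kind):
        out["id"].append(cid)
        out["core"].append(core)
        out["fragment"].append(frag)
        out["core_heavy"].append(ch)
        out["frag_heavy"].append(fh)
        out["a1"].append(a1)
        out["a2"].append(a2)
        out["kind"].append(kind)

    for rec in payload["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            raise ValueError("unparsable SMILES in cuts: %s" % rec["smiles"])
        cid = rec["id"]
        for b in cleavable_bonds(mol):
            (smi_b, h_b), (smi_e, h_e) = split_on_bond(mol, b)
            a1, a2 = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
            # both orientations: each side serves once as the fragment
            emit(cid, smi_b, smi_e, h_b, h_e, a1, a2, "bond")
            emit(cid, smi_e, smi_b, h_e, h_b, a1, a2, "bond")
        if hydrogen:
            seen = set()
            for atom in mol.GetAtoms():
                if atom.GetAtomicNum() <= 1 or atom.GetTotalNumHs() == 0:
                    continue
                rw = Chem.RWMol(mol)
                d = rw.AddAtom(Chem.Atom(0))
                rw.AddBond(atom.GetIdx(), d, Chem.BondType.SINGLE)
                core = rw.GetMol()
                try:
                    Chem.SanitizeMol(core)
                except Exception:
                    continue
                can = Chem.MolToSmiles(core)
                if can in seen:  # symmetry-equivalent position
                    continue
                seen.add(can)
                emit(cid, can, H_FRAGMENT, heavy_count(core), 0,
                     atom.GetIdx(), -1, "hydrogen")
    return out


def op_cut_bond(payload):
    """Cut one specific bond (any order) — used for non-single retro rules."""
    out = {"id": [], "core": [], "fragment": [], "core_heavy": [],
           "frag_heavy": [], "a1": [], "a2": [], "kind": []}
    for rec in payload["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            raise ValueError("unparsable SMILES in cut_bond")
        b = mol.GetBondBetweenAtoms(int(rec["a1"]), int(rec["a2"]))
        if b is None or b.IsInRing():
            raise ValueError("no acyclic bond between atoms %s-%s"
                             % (rec["a1"], rec["a2"]))
        (smi_b, h_b), (smi_e, h_e) = split_on_bond(mol, b)
        for core, frag, ch, fh in ((smi_b, smi_e, h_b, h_e),
                                   (smi_e, smi_b, h_e, h_b)):
            out["id"].append(rec["id"])
            out["core"].append(core)
            out["fragment"].append(frag)
            out["core_heavy"].append(ch)
            out["frag_heavy"].append(fh)
            out["a1"].append(int(rec["a1"]))
            out["a2"].append(int(rec["a2"]))
            out["kind"].append("bond")
    return out


def attach_map(mol):
    for a in mol.GetAtoms():
        if a.GetAtomicNum() == 0:
            a.SetAtomMapNum(1)
    return mol


def op_reassemble(payload):
    out = {"smiles": [], "error": []}
    for rec in payload["records"]:
        try:
            core = Chem.MolFromSmiles(rec["core"])
            if core is None:
                raise ValueError("unparsable core: %s" % rec["core"])
            if rec["fragment"] == H_FRAGMENT:
                rw = Chem.RWMol(core)
                dummies = [a.GetIdx() for a in rw.GetAtoms()
                           if a.GetAtomicNum() == 0]
                if len(dummies) != 1:
                    raise ValueError("core must carry exactly one attachment")
                rw.RemoveAtom(dummies[0])
                mol = rw.GetMol()
                Chem.SanitizeMol(mol)
            else:
                frag = Chem.MolFromSmiles(rec["fragment"])
                if frag is None:
                    raise ValueError("unparsable fragment: %s"
                                     % rec["fragment"])
                for part, label in ((core, "core"), (frag, "fragment")):
                    nd = sum(1 for a in part.GetAtoms()
                             if a.GetAtomicNum() == 0)
                    if nd != 1:
                        raise ValueError(
                            "%s must carry exactly one attachment" % label)
                mol = Chem.molzip(Chem.CombineMols(attach_map(core),
                                                   attach_map(frag)))
                Chem.SanitizeMol(mol)
            out["smiles"].append(Chem.MolToSmiles(mol))
            out["error"].append("")
        except Exception as exc:
            out["smiles"].append(None)
            out["error"].append(str(exc))
    return out


def op_retro_bonds(payload):
    rules = []
    for r in payload["rules"]:
        patt = Chem.MolFromSmarts(r["smarts"])
        if patt is None:
            raise ValueError("malformed SMARTS for rule '%s': %s"
                             % (r["rule_id"], r["smarts"]))
        pos = {}
        for qa in patt.GetAtoms():
            if qa.GetAtomMapNum() in (1, 2):
                pos[qa.GetAtomMapNum()] = qa.GetIdx()
        if set(pos) != {1, 2}:
            raise ValueError("rule '%s' must map exactly atoms :1 and :2"
                             % r["rule_id"])
        rules.append((r["rule_id"], patt, pos[1], pos[2]))

    out = {"id": [], "rule_id": [], "a1": [], "a2": [], "bond_order": []}
    for rec in payload["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            raise ValueError("unparsable SMILES in retro_bonds")
        seen = set()
        for rule_id, patt, p1, p2 in rules:
            for match in mol.GetSubstructMatches(patt, uniquify=False):
                i, j = match[p1], match[p2]
                bond = mol.GetBondBetweenAtoms(i, j)
                if bond is None or bond.IsInRing():
                    continue
                a1, a2 = (i, j) if i < j else (j, i)
                key = (rule_id, a1, a2)
                if key in seen:
                    continue
                seen.add(key)
                out["id"].append(rec["id"])
                out["rule_id"].append(rule_id)
                out["a1"].append(a1)
                out["a2"].append(a2)
                out["bond_order"].append(int(bond.GetBondTypeAsDouble()))
    return out


OPS = {
    "standardize": op_standardize,
    "heavy_atoms": op_heavy_atoms,
    "cuts": op_cuts,
    "cut_bond": op_cut_bond,
    "reassemble": op_reassemble,
    "retro_bonds": op_retro_bonds,
}


def main():
    req = json.load(sys.stdin)
    try:
        op = req["op"]
        if op not in OPS:
            raise ValueError("unknown op: %s" % op)
        result = OPS[op](req.get("payload", {}))
        resp = {"ok": True, "result": result}
    except Exception as exc:
        resp = {"ok": False, "error": str(exc)}
    json.dump(resp, sys.stdout)
    sys.stdout.write("\n")


if __name__ == "__main__":
    main()
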