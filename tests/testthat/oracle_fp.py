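"""Independent reference implementation of the circular fingerprint.

Implements the documented algorithm — FNV-1a 32-bit hashing of per-atom
invariants (element, heavy degree, formal charge, attached hydrogens, ring
membership), iterated over sorted neighbor identifiers, folded modulo
n_bits — on RDKit's molecule graph, independently of the R implementation
(different parser, different language, separately written hashing).

Modes (one request per input line, results one per output line):
  fp <smiles> <radius> <n_bits>   -> comma-separated sorted on-bit positions
  respell <smiles> <n> <seed>     -> space-separated random SMILES spellings
  canon_len <smiles>              -> RDKit canonical SMILES (sanity helper)
"""
import sys

from rdkit import Chem


def fnv1a32(s: str) -> int:
    h = 2166136261
    for b in s.encode("utf-8"):
        h ^= b
        h = (h * 16777619) % 2**32
    return h


def fingerprint_bits(smiles: str, radius: int, n_bits: int):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError(f"unparseable SMILES: {smiles}")
    atoms = list(mol.GetAtoms())
    ids = []
    nbrs = []
    for a in atoms:
        heavy = [n for n in a.GetNeighbors() if n.GetAtomicNum() > 1]
        nbrs.append([n.GetIdx() for n in heavy])
        inv = "|".join(
            [
                a.GetSymbol(),
                str(len(heavy)),
                str(a.GetFormalCharge()),
                str(a.GetTotalNumHs()),
                str(int(a.IsInRing())),
            ]
        )
        ids.append(fnv1a32(inv))
    all_ids = list(ids)
    for r in range(1, radius + 1):
        new_ids = []
        for i in range(len(atoms)):
            nb = sorted(ids[j] for j in nbrs[i])
            s = f"{r}|{ids[i]}|{','.join(str(x) for x in nb)}"
            new_ids.append(fnv1a32(s))
        ids = new_ids
        all_ids.extend(ids)
    return sorted({i % n_bits for i in all_ids})


def respell(smiles: str, n: int, seed: int):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError(f"unparseable SMILES: {smiles}")
    return list(Chem.MolToRandomSmilesVect(mol, n, randomSeed=seed))


def main():
    from rdkit import RDLogger

    RDLogger.DisableLog("rdApp.*")

    for line in sys.stdin:
        parts = line.split()
        if not parts:
            continue
        mode = parts[0]
        if mode == "fp":
            bits = fingerprint_bits(parts[1], int(parts[2]), int(parts[3]))
            print(",".join(str(b) for b in bits))
        elif mode == "respell":
            print(" ".join(respell(parts[1], int(parts[2]), int(parts[3]))))
        elif mode == "canon_len":
            print(Chem.MolToSmiles(Chem.MolFromSmiles(parts[1])))
        else:
            raise ValueError(f"unknown mode: {mode}")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
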