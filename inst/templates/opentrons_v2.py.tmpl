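"""{{PROTOCOL_NAME}} - compiled liquid-handling protocol.

Generated protocol: a fixed interpreter over an inlined instruction plan.
The plan below is data, not code; audit or diff it directly.
"""
import json

from opentrons import protocol_api

metadata = {
    "protocolName": "{{PROTOCOL_NAME}}",
    "description": "Compiled Golden Gate / colony PCR instruction plan",
}

requirements = {"robotType": "{{ROBOT_TYPE}}", "apiLevel": "{{API_LEVEL}}"}

_PLAN_TEXT = r"""
# -- PLAN-BEGIN --
{{PLAN_JSON}}
# -- PLAN-END --
"""

PLAN = json.loads("\n".join(
    line for line in _PLAN_TEXT.splitlines() if not line.startswith("#")))

_LABWARE_DEFS = {
    "96_well_pcr_plate": "nest_96_wellplate_100ul_pcr_full_skirt",
    "96_well_flat_plate": "corning_96_wellplate_360ul_flat",
    "tube_rack_2ml": "opentrons_24_tuberack_nest_2ml_snapcap",
    "temperature_module": "opentrons_24_aluminumblock_nest_2ml_snapcap",
    "mix_reservoir": "nest_12_reservoir_15ml",
    "6_well_agar_plate": "corning_6_wellplate_16.8ml_flat",
    "tip_rack": None,  # resolved per pipette below
}

_TIP_DEFS = {
    "p20_single_gen2": "opentrons_96_tiprack_20ul",
    "p300_single_gen2": "opentrons_96_tiprack_300ul",
    "flex_1channel_50": "opentrons_flex_96_tiprack_50ul",
    "flex_1channel_1000": "opentrons_flex_96_tiprack_1000ul",
}


def run(protocol: protocol_api.ProtocolContext):
    deck = PLAN["deck"]
    labware = {}
    modules = {}
    tip_kind = _TIP_DEFS[sorted(
        {i["pipette"] for i in PLAN["instructions"]
         if i.get("pipette")} or {"p20_single_gen2"})[0]]

    for slot, occ in deck["slots"].items():
        if occ == "empty":
            continue
        typ, lab = occ["type"], occ["labware_id"]
        if typ == "thermocycler":
            if "thermocycler" not in modules:
                modules["thermocycler"] = protocol.load_module(
                    "thermocyclerModuleV2")
            continue
        if typ == "temperature_module":
            modules["temperature"] = protocol.load_module(
                "temperature module gen2", slot)
            labware[lab] = modules["temperature"].load_labware(
                _LABWARE_DEFS["temperature_module"])
            continue
        if typ == "tip_rack":
            labware[lab] = protocol.load_labware(tip_kind, slot)
            continue
        labware[lab] = protocol.load_labware(_LABWARE_DEFS[typ], slot)
    if "thermocycler" in modules:
        labware["reaction_plate"] = modules["thermocycler"].load_labware(
            _LABWARE_DEFS["96_well_pcr_plate"])

    pipettes = {}
    racks = [labware[r["labware_id"]] for r in deck["tip_racks"]]
    for name in sorted({i["pipette"] for i in PLAN["instructions"]
                        if i.get("pipette")}):
        pipettes[name] = protocol.load_instrument(
            name, "left" if not pipettes else "right", tip_racks=racks)

    def well_of(ins):
        return labware[ins["labware"]][ins["well"]]

    for ins in PLAN["instructions"]:
        kind = ins["kind"]
        pip = pipettes.get(ins.get("pipette"))
        if kind == "move":
            continue  # movement is implicit in the API calls below
        if kind == "pick_tip":
            pip.pick_up_tip()
        elif kind == "drop_tip":
            pip.drop_tip()
        elif kind == "aspirate":
            pip.aspirate(ins["volume_ul"], well_of(ins))
        elif kind == "dispense":
            dst = well_of(ins)
            off = ins.get("offset_mm") or [None, None, None]
            if off[0] is not None:
                dst = dst.top().move(
                    protocol_api.labware.types.Point(off[0], off[1], off[2]))
            pip.dispense(ins["volume_ul"], dst)
        elif kind == "mix":
            pip.mix(3, ins["volume_ul"], well_of(ins))
        elif kind == "set_temperature":
            if ins["labware"] == "temperature_module":
                modules["temperature"].set_temperature(ins["volume_ul"])
            elif "thermocycler" in modules:
                modules["thermocycler"].set_lid_temperature(ins["volume_ul"])
        elif kind == "thermal_step":
            protocol.comment("thermal: " + ins.get("comment", ""))
        elif kind == "pause_for_operator":
            protocol.pause(ins.get("comment", "operator action required"))
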