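<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_E_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" name="extracellular" constant="true"/>
      <compartment id="c" name="cytosol" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="lcts_e" name="lactose" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="o2_e" name="oxygen" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="ac_e" name="acetate" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="met_e" name="methionine" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="lcts_c" name="lactose" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="o2_c" name="oxygen" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="ac_c" name="acetate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="met_c" name="methionine" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="atp_c" name="ATP" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="adp_c" name="ADP" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_free" value="-1000" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="lb_atpm" value="2" constant="true"/>
      <parameter id="ub_free" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_lcts" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="lcts_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_o2" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="o2_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_ac" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="ac_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_met" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="met_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="T_lcts" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="lcts_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="lcts_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="T_o2" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="o2_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="o2_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="T_ac" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="ac_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ac_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="T_met" reversible="true" fast="false" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="met_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="met_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="AERO" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="lcts_c" stoichiometry="1" constant="true"/>
          <speciesReference species="o2_c" stoichiometry="2" constant="true"/>
          <speciesReference species="adp_c" stoichiometry="6" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="atp_c" stoichiometry="6" constant="true"/>
          <speciesReference species="ac_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="FERM" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="lcts_c" stoichiometry="1" constant="true"/>
          <speciesReference species="adp_c" stoichiometry="2" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="atp_c" stoichiometry="2" constant="true"/>
          <speciesReference species="ac_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="ATPM" reversible="false" fast="false" fbc:lowerFluxBound="lb_atpm" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="atp_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="adp_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="atp_c" stoichiometry="10" constant="true"/>
          <speciesReference species="met_c" stoichiometry="0.15" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="adp_c" stoichiometry="10" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
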